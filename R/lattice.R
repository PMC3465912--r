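#' Positions of RyR clusters on the regular release lattice
#'
#' Clusters sit at interior lattice points `x = l_x * i` (i = 1..Lx/l_x - 1),
#' `y = l_y * j` (j = 1..Ly/l_y - 1): at the default geometry (100 x 20 um,
#' l_x = 2, l_y = 1) this yields the 49 x 19 = 931 clusters of the release
#' network.
#'
#' @param grid a [grid_params()] object.
#' @return a two-column matrix (`x`, `y`) of positions in um, row-major in y
#'   then x (x fastest).
#' @export
build_cluster_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_params"))
  tol <- 1e-9
  nx <- grid$Lx / grid$l_x
  ny <- grid$Ly / grid$l_y
  if (abs(nx - round(nx)) > tol || abs(ny - round(ny)) > tol)
    stop("build_cluster_grid: domain size must be divisible by cluster spacing (ambiguous lattice)",
         call. = FALSE)
  nx <- round(nx) - 1L
  ny <- round(ny) - 1L
  if (nx < 1 || ny < 1)
    stop("build_cluster_grid: no interior lattice points (domain too small for spacing)",
         call. = FALSE)
  pos <- cbind(
    x = rep(grid$l_x * seq_len(nx), times = ny),
    y = rep(grid$l_y * seq_len(ny), each = nx)
  )
  pos
}

#' Random placement of rogue RyR channels
#'
#' Rogue (solitary) RyRs are scattered i.i.d. uniformly over the sheet; the
#' count is `round(N_rogue * Lx * Ly)` (2000 channels at 1 channel/um^2 on the
#' default 100 x 20 um sheet).
#'
#' @param n_rogue density in channels/um^2 (>= 0).
#' @param grid a [grid_params()] object.
#' @param seed integer seed making the placement reproducible.
#' @return a two-column matrix (`x`, `y`) of positions in um.
#' @export
place_rogues <- function(n_rogue, grid, seed) {
  stopifnot(inherits(grid, "grid_params"))
  if (!is.numeric(n_rogue) || length(n_rogue) != 1 || is.na(n_rogue) || n_rogue < 0)
    stop("place_rogues: n_rogue must be a single non-negative number", call. = FALSE)
  n <- round(n_rogue * grid$Lx * grid$Ly)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cbind(x = stats::runif(n, 0, grid$Lx), y = stats::runif(n, 0, grid$Ly))
}

#' Luminal gating factor k_CaSR
#'
#' SR-load dependence of the firing probability:
#' `k_CaSR = k_max / (1 + (D_SR / Ca_SR)^n_SR)`, a saturating Hill function of
#' luminal Ca2+ with half-maximum at `Ca_SR = D_SR` and limit `k_max` (= 2 by
#' default).
#'
#' @param ca_sr luminal SR Ca2+ concentration (mM), > 0 (vectorised).
#' @param p a [release_params()] object.
#' @return dimensionless factor in (0, k_max), strictly increasing in `ca_sr`.
#' @export
luminal_factor <- function(ca_sr, p) {
  stopifnot(inherits(p, "release_params"))
  if (!is.numeric(ca_sr) || any(!is.finite(ca_sr)) || any(ca_sr <= 0))
    stop("luminal_factor: ca_sr must be positive", call. = FALSE)
  p$k_max / (1 + (p$D_SR / ca_sr)^p$n_SR)
}

#' Firing probability of a RyR cluster or rogue channel
#'
#' Per-millisecond opening probability
#' `P_j = P_max / (1 + (K_mj / Ca_local)^n_j) * k_CaSR(Ca_SR)`, with
#' `n_cluster = 1.6` for the cooperatively gating cluster and `n_rogue = 1.0`
#' for the solitary channel.  At cytosolic and luminal half-saturation this is
#' `P_max/2 * 1 = 0.15` /ms; the saturated ceiling is `P_max * k_max = 0.6` /ms.
#'
#' @param ca_local local cytosolic Ca2+ at the channel (mM), > 0 (vectorised).
#' @param ca_sr luminal SR Ca2+ (mM), > 0.
#' @param kind `"cluster"` or `"rogue"`.
#' @param p a [release_params()] object.
#' @return opening probability per ms.
#' @export
firing_probability <- function(ca_local, ca_sr, kind = c("cluster", "rogue"), p) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "release_params"))
  if (!is.numeric(ca_local) || any(!is.finite(ca_local)) || any(ca_local <= 0))
    stop("firing_probability: ca_local must be positive", call. = FALSE)
  km <- if (kind == "cluster") p$K_m_cluster else p$K_m_rogue
  n  <- if (kind == "cluster") p$n_cluster else p$n_rogue
  p$P_max / (1 + (km / ca_local)^n) * luminal_factor(ca_sr, p)
}

#' Assemble a RyR lattice (clusters + rogues) with per-channel state
#'
#' Builds the cluster grid and random rogue placement for a given geometry and
#' density, snapping every channel to its nearest field mesh node (clusters lie
#' on mesh-commensurate coordinates at the default spacings).  Channel state is
#' `"closed"`, `"open"` or `"refractory"` with a remaining-time counter (ms).
#'
#' @inheritParams place_rogues
#' @param release a [release_params()] object (open/refractory durations).
#' @return an object of class `ryr_lattice` with elements `cluster_pos`,
#'   `rogue_pos` (um), `cluster_node`, `rogue_node` (1-based `(ix, iy)` mesh
#'   indices), `cluster_state`, `rogue_state` (integer: 0 closed, 1 open,
#'   2 refractory), `cluster_timer`, `rogue_timer` (ms remaining in the
#'   current open/refractory phase).
#' @export
ryr_lattice <- function(n_rogue, grid, release, seed) {
  stopifnot(inherits(grid, "grid_params"), inherits(release, "release_params"))
  cl <- build_cluster_grid(grid)
  ro <- place_rogues(n_rogue, grid, seed)
  snap <- function(pos) {
    cbind(ix = pmin(round(grid$Lx / grid$h), pmax(0, round(pos[, 1] / grid$h))) + 1L,
          iy = pmin(round(grid$Ly / grid$h), pmax(0, round(pos[, 2] / grid$h))) + 1L)
  }
  lat <- list(
    cluster_pos = cl, rogue_pos = ro,
    cluster_node = snap(cl), rogue_node = snap(ro),
    cluster_state = integer(nrow(cl)), rogue_state = integer(nrow(ro)),
    cluster_timer = numeric(nrow(cl)), rogue_timer = numeric(nrow(ro)),
    n_rogue = n_rogue, seed = seed,
    release = release, grid = grid
  )
  class(lat) <- "ryr_lattice"
  lat
}

#' Advance stochastic channel states by one gating interval
#'
#' Each closed, non-refractory channel opens with probability `P_j * dt`
#' evaluated at the Ca2+ of its nearest mesh node; open channels close after
#' their fixed open duration and enter a refractory period.  Channel order is
#' fixed (clusters row-major, then rogues by index) so that, given the R RNG
#' state, the update is reproducible.
#'
#' @param lattice an [ryr_lattice()] object.
#' @param ca_field matrix of cytosolic Ca2+ (mM), dimensions
#'   `(Lx/h + 1) x (Ly/h + 1)`.
#' @param ca_sr luminal SR Ca2+ (mM).
#' @param dt gating interval (ms); `P_j * dt` must be <= 1.
#' @return the updated lattice, with attribute `"opened"`: a list with indices
#'   of newly opened clusters and rogues.
#' @export
advance_states <- function(lattice, ca_field, ca_sr, dt) {
  stopifnot(inherits(lattice, "ryr_lattice"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("advance_states: dt must be positive", call. = FALSE)
  p <- lattice$release
  if (p$P_max * p$k_max * dt > 1)
    stop("advance_states: firing probability * dt exceeds 1; use a smaller dt",
         call. = FALSE)
  step_kind <- function(state, timer, node, kind, t_open) {
    if (!length(state)) return(list(state = state, timer = timer, opened = integer(0)))
    # expire open -> refractory, refractory -> closed
    timer <- timer - dt
    to_refr <- state == 1L & timer <= 0
    state[to_refr] <- 2L
    timer[to_refr] <- p$t_refractory
    to_closed <- state == 2L & timer <= 0 & !to_refr
    state[to_closed] <- 0L
    timer[to_closed] <- 0
    closed <- which(state == 0L)
    opened <- integer(0)
    if (length(closed)) {
      ca_loc <- ca_field[cbind(node[closed, 1], node[closed, 2])]
      ca_loc <- pmax(ca_loc, 1e-12)
      pj <- firing_probability(ca_loc, ca_sr, kind, p)
      if (any(pj * dt > 1))
        stop("advance_states: P_j * dt > 1 at some site; use a smaller dt",
             call. = FALSE)
      u <- stats::runif(length(closed))
      opened <- closed[u < pj * dt]
      state[opened] <- 1L
      timer[opened] <- t_open
    }
    list(state = state, timer = timer, opened = opened)
  }
  cl <- step_kind(lattice$cluster_state, lattice$cluster_timer,
                  lattice$cluster_node, "cluster", p$t_open_cluster)
  ro <- step_kind(lattice$rogue_state, lattice$rogue_timer,
                  lattice$rogue_node, "rogue", p$t_open_rogue)
  lattice$cluster_state <- cl$state
  lattice$cluster_timer <- cl$timer
  lattice$rogue_state <- ro$state
  lattice$rogue_timer <- ro$timer
  attr(lattice, "opened") <- list(clusters = cl$opened, rogues = ro$opened)
  lattice
}

#' @export
print.ryr_lattice <- function(x, ...) {
  cat("<ryr_lattice>", nrow(x$cluster_pos), "clusters,",
      nrow(x$rogue_pos), sprintf("rogues (N_rogue = %g /um^2, seed %s)\n",
                                 x$n_rogue, format(x$seed)))
  invisible(x)
}
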