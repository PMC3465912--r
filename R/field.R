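#' Initialise the subcellular Ca2+ field
#'
#' Uniform resting free Ca2+ with indicator dye and stationary endogenous
#' buffer at binding equilibrium.  Node counts are `Lx/h + 1` by `Ly/h + 1`
#' (boundary nodes included; zero-flux boundaries).
#'
#' @param grid a [grid_params()] object.
#' @param ca0 resting free Ca2+ (mM), typically the cell model's resting value.
#' @return an object of class `ca_field`: list with matrices `ca`, `dye_b`
#'   (dye-bound Ca2+), `buf_b` (buffer-bound Ca2+), all `nx x ny` in mM, plus
#'   `nx`, `ny` and the grid.
#' @export
ca_field_init <- function(grid, ca0 = 7e-5) {
  stopifnot(inherits(grid, "grid_params"), ca0 > 0)
  nx <- round(grid$Lx / grid$h) + 1L
  ny <- round(grid$Ly / grid$h) + 1L
  kd_dye <- grid$dye_koff / grid$dye_kon
  kd_buf <- grid$buf_koff / grid$buf_kon
  f <- list(
    ca    = matrix(ca0, nx, ny),
    dye_b = matrix(grid$dye_total * ca0 / (ca0 + kd_dye), nx, ny),
    buf_b = matrix(grid$buf_total * ca0 / (ca0 + kd_buf), nx, ny),
    nx = nx, ny = ny, grid = grid
  )
  class(f) <- "ca_field"
  f
}

#' Field SERCA pump rate and the leak that balances it at rest
#'
#' The subcellular uptake is a Hill function
#' `J_pump = Vmax * ca^n / (ca^n + Km^n)`; the RyR-independent background leak
#' is the constant that balances the pump exactly at the resting Ca2+, so an
#' undisturbed field is stationary.
#'
#' @param ca free Ca2+ (mM), vectorised.
#' @param grid a [grid_params()] object.
#' @return pump rate (mM/ms).
#' @export
field_pump <- function(ca, grid) {
  can <- ca^grid$pump_hill
  grid$pump_vmax * can / (can + grid$pump_km^grid$pump_hill)
}

#' @rdname field_pump
#' @param ca0 resting free Ca2+ (mM).
#' @export
field_leak <- function(grid, ca0 = 7e-5) {
  if (is.finite(grid$leak)) grid$leak else field_pump(ca0, grid)
}

#' Ca2+ release flux through an open RyR cluster
#'
#' `J_cluster = V_cluster * (Ca_SR - Ca_node)` in pmol/ms, clamped at zero when
#' the gradient reverses (release channels do not pump Ca2+ back into the SR).
#'
#' @param ca_sr luminal SR Ca2+ (mM).
#' @param ca_node cytosolic Ca2+ at the cluster's node (mM).
#' @param p a [release_params()] object.
#' @return flux in pmol/ms (vectorised over `ca_node`).
#' @export
cluster_flux <- function(ca_sr, ca_node, p) {
  stopifnot(inherits(p, "release_params"))
  pmax(0, p$V_cluster * (ca_sr - ca_node))
}

#' Ca2+ release flux through a rogue RyR channel
#'
#' The fixed quark-scale flux `J_rogue_amp` (pmol/ms) while open, zero while
#' closed.
#'
#' @param open logical (vectorised): channel open?
#' @param p a [release_params()] object.
#' @return flux in pmol/ms.
#' @export
rogue_flux <- function(open, p) {
  stopifnot(inherits(p, "release_params"))
  ifelse(open, p$J_rogue_amp, 0)
}

#' Convert a point release flux to a mesh-node concentration rate
#'
#' The single audited unit bridge between channel fluxes (pmol/ms) and field
#' source terms (mM/ms): a flux J into one voxel of volume `h^2 * depth` um^3
#' raises its concentration at `J * 1e6 / (h^2 * depth)` mM/ms
#' (1 pmol / 1 nL = 1 mM; 1 um^3 = 1e-6 nL).
#'
#' @param j_pmol flux in pmol/ms (vectorised).
#' @param grid a [grid_params()] object (`h`, `depth`).
#' @return concentration rate in mM/ms.
#' @export
flux_to_node_rate <- function(j_pmol, grid) {
  j_pmol * 1e6 / (grid$h^2 * grid$depth)
}

# Integer node offsets covering a disc of physical radius r (um), weighted by
# the fraction of each voxel's area inside the disc (7x7 subsampling).
# Cluster release is spread over this fixed physical footprint so that spark
# amplitude is mesh-robust; the weights sum to one.
footprint_offsets <- function(grid, r) {
  m <- ceiling(r / grid$h + 0.5)
  g <- expand.grid(dx = -m:m, dy = -m:m)
  sub <- (seq_len(7) - 4) / 7
  frac <- mapply(function(dx, dy) {
    d2 <- outer((dx + sub) * grid$h, (dy + sub) * grid$h,
                function(a, b) a^2 + b^2)
    mean(d2 <= r^2)
  }, g$dx, g$dy)
  keep <- frac > 0
  g <- g[keep, , drop = FALSE]
  frac <- frac[keep]
  if (!nrow(g)) {
    g <- data.frame(dx = 0L, dy = 0L)
    frac <- 1
  }
  g$w <- frac / sum(frac)
  g
}

#' Build the release source map for the current channel states
#'
#' Maps every open channel's flux onto mesh nodes: cluster fluxes (dependent on
#' the SR-cytosol gradient at the cluster's node) are spread uniformly over a
#' disc of radius `r_source`; rogue fluxes are point sources at their node.
#' Also accumulates the whole-field flux total used for the cellular release
#' current.
#'
#' @param lattice an [ryr_lattice()] object (with current states).
#' @param field a [ca_field_init()] object.
#' @param ca_sr luminal SR Ca2+ (mM).
#' @return an object of class `release_flux_map`: list with `src` (nx x ny
#'   matrix, mM/ms), `J_cluster`, `J_rogue` (per-open-channel fluxes, pmol/ms)
#'   and `J_total` (pmol/ms).
#' @export
source_map <- function(lattice, field, ca_sr) {
  stopifnot(inherits(lattice, "ryr_lattice"), inherits(field, "ca_field"))
  grid <- lattice$grid
  p <- lattice$release
  src <- matrix(0, field$nx, field$ny)
  open_cl <- which(lattice$cluster_state == 1L)
  open_ro <- which(lattice$rogue_state == 1L)
  jc <- numeric(0); jr <- numeric(0)
  if (length(open_cl)) {
    node <- lattice$cluster_node[open_cl, , drop = FALSE]
    ca_node <- field$ca[cbind(node[, 1], node[, 2])]
    jc <- cluster_flux(ca_sr, ca_node, p)
    fp <- footprint_offsets(grid, p$r_source)
    for (k in seq_along(open_cl)) {
      ix <- pmin(field$nx, pmax(1L, node[k, 1] + fp$dx))
      iy <- pmin(field$ny, pmax(1L, node[k, 2] + fp$dy))
      rate <- flux_to_node_rate(jc[k] * fp$w, grid)
      src[cbind(ix, iy)] <- src[cbind(ix, iy)] + rate
    }
  }
  if (length(open_ro)) {
    node <- lattice$rogue_node[open_ro, , drop = FALSE]
    jr <- rep(p$J_rogue_amp, length(open_ro))
    rate <- flux_to_node_rate(jr, grid)
    for (k in seq_along(open_ro))
      src[node[k, 1], node[k, 2]] <- src[node[k, 1], node[k, 2]] + rate[k]
  }
  out <- list(src = src, J_cluster = jc, J_rogue = jr,
              J_total = sum(jc) + sum(jr))
  class(out) <- "release_flux_map"
  out
}

#' Whole-field release flux total in cellular units
#'
#' Sums all active cluster and rogue source strengths and converts the total
#' to a cytosolic concentration rate of the whole-cell model
#' (`J_total [pmol/ms] / V_c [nL] = mM/ms`).  Multiplying by `k_rel` (see
#' [couple_release()]) gives the release current consumed by the cell model.
#'
#' @param fluxes a [source_map()] result (`release_flux_map`).
#' @param membrane a [membrane_params()] object (cytosolic volume `V_c`).
#' @return scalar release flux in cytosolic mM/ms.
#' @export
subrel_total <- function(fluxes, membrane) {
  stopifnot(inherits(fluxes, "release_flux_map"),
            inherits(membrane, "membrane_params"))
  fluxes$J_total / membrane$V_c
}

#' Advance the reaction-diffusion field by one explicit step
#'
#' One forward-Euler step of the cytosolic Ca2+ balance: anisotropic 5-point
#' Laplacian (`D_x`, `D_y`) with zero-flux boundaries, mass-action dye and
#' stationary-buffer kinetics, Hill-type SERCA uptake, constant background
#' leak, and the release source map.  Dye (free and bound) diffuses with
#' `D_dye`; the endogenous buffer is immobile.
#'
#' @param field a [ca_field_init()] object.
#' @param src `nx x ny` source matrix in mM/ms (e.g. from [source_map()]), or
#'   `NULL` for none.
#' @param dt time step (ms); must satisfy the stability bound of the grid.
#' @param leak background leak (mM/ms); default balances the pump at 7e-5 mM.
#' @return the updated `ca_field`.
#' @export
step_field <- function(field, src = NULL, dt = field$grid$dt,
                       leak = field_leak(field$grid)) {
  stopifnot(inherits(field, "ca_field"))
  g <- field$grid
  if (dt * (g$D_x + g$D_y) / g$h^2 > 0.5)
    stop("step_field: dt violates the explicit stability bound", call. = FALSE)
  ca <- field$ca; db <- field$dye_b; bb <- field$buf_b
  lap <- function(m, Dx, Dy) {
    nx <- nrow(m); ny <- ncol(m)
    xm <- m[c(1L, seq_len(nx - 1L)), ]       # reflected left neighbour
    xp <- m[c(seq_len(nx)[-1L], nx), ]       # reflected right neighbour
    ym <- m[, c(1L, seq_len(ny - 1L))]
    yp <- m[, c(seq_len(ny)[-1L], ny)]
    (Dx * (xm + xp - 2 * m) + Dy * (ym + yp - 2 * m)) / g$h^2
  }
  r_dye <- g$dye_kon * ca * (g$dye_total - db) - g$dye_koff * db
  r_buf <- g$buf_kon * ca * (g$buf_total - bb) - g$buf_koff * bb
  pump <- field_pump(ca, g)
  dca <- lap(ca, g$D_x, g$D_y) - r_dye - r_buf - pump + leak
  if (!is.null(src)) dca <- dca + src
  ca_new <- ca + dt * dca
  db_new <- db + dt * (lap(db, g$D_dye, g$D_dye) + r_dye)
  bb_new <- bb + dt * r_buf
  if (anyNA(ca_new) || any(!is.finite(ca_new))) {
    bad <- which(!is.finite(ca_new), arr.ind = TRUE)[1, ]
    stop(sprintf("step_field: non-finite concentration at node (%d, %d)",
                 bad[1], bad[2]), call. = FALSE)
  }
  field$ca <- pmax(ca_new, 0)
  field$dye_b <- pmax(db_new, 0)
  field$buf_b <- pmax(bb_new, 0)
  field
}

#' @export
print.ca_field <- function(x, ...) {
  cat("<ca_field>", x$nx, "x", x$ny, "nodes, h =", x$grid$h,
      "um; mean free Ca =", format(mean(x$ca), digits = 4), "mM\n")
  invisible(x)
}
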