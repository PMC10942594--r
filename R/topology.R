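#' Default wiring constants of the hippocampal formation
#'
#' Returns the built-in wiring tables: population sizes per area, intra-area
#' maximum connection probabilities and conductance increments per ordered
#' class pair, inter-area connection strengths (probability amplitudes of the
#' z-distance kernel) and their increments, and the spatial kernel widths.
#' Inter-area projections are excitatory only and follow the canonical
#' wiring: tri-synaptic EC-DG-CA3-CA1, monosynaptic EC-CA3 and EC-CA1, and
#' the CA1-EC feedback that closes the hippocampal-entorhinal loop.
#'
#' @return a list with elements `sizes`, `intra_prob`, `intra_increment_ps`,
#'   `inter_gain`, `inter_increment_ps`, `sigma_um`.
#' @export
wiring_defaults <- function() {
  areas <- c("EC", "DG", "CA3", "CA1")
  sizes <- data.frame(area = areas,
                      n_exc = c(10000L, 10000L, 1000L, 10000L),
                      n_inh = c(1000L, 100L, 100L, 1000L))
  intra_prob <- matrix(c(0, 0.37, 0.54, 0,
                         0, 0.06, 0.14, 0,
                         0.56, 0.75, 0.75, 0,
                         0, 0.28, 0.30, 0.70),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(areas, c("EE", "EI", "IE", "II")))
  intra_inc <- matrix(c(0, 20, 600, 0,
                        0, 180, 1800, 0,
                        20, 20, 600, 0,
                        0, 60, 1800, 1800),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(areas, c("EE", "EI", "IE", "II")))
  inter_gain <- matrix(0, 4, 4, dimnames = list(areas, areas))
  inter_gain["EC", "DG"] <- 13.0
  inter_gain["EC", "CA3"] <- 0.14
  inter_gain["EC", "CA1"] <- 1.1
  inter_gain["DG", "CA3"] <- 0.14
  inter_gain["CA3", "CA1"] <- 1.1
  inter_gain["CA1", "EC"] <- 0.2
  inter_inc <- matrix(0, 4, 4, dimnames = list(areas, areas))
  inter_inc["EC", "DG"] <- 20
  inter_inc["EC", "CA3"] <- 20
  inter_inc["EC", "CA1"] <- 20
  inter_inc["DG", "CA3"] <- 180
  inter_inc["CA3", "CA1"] <- 20
  inter_inc["CA1", "EC"] <- 60
  list(sizes = sizes, intra_prob = intra_prob, intra_increment_ps = intra_inc,
       inter_gain = inter_gain, inter_increment_ps = inter_inc,
       sigma_um = c(intra_exc = 2500, intra_inh = 350, inter = 1000))
}

#' Mean Gaussian kernel mass over a uniform z-interval
#'
#' For two independent positions uniform on `[0, L]`,
#' \eqn{E[e^{-(z_1-z_2)^2/2\sigma^2}]} in closed form.  Used to conserve the
#' mean synaptic drive per neuron when the slice is scaled down.
#'
#' @param l_um interval length.
#' @param sigma_um kernel width.
#' @return expected kernel value in `(0, 1]`.
#' @export
z_kernel_mean <- function(l_um, sigma_um) {
  if (l_um <= 0) return(1)
  x <- l_um / sigma_um
  erf <- function(u) 2 * stats::pnorm(u * sqrt(2)) - 1
  sqrt(2 * pi) / x * erf(x / sqrt(2)) - 2 / x^2 * (1 - exp(-x^2 / 2))
}

# mean of min(1, a * exp(-dz^2 / 2 sigma^2)) over pair distances dz of two
# independent uniforms on [0, l]; the clipped version of z_kernel_mean()
.clipped_kernel_mean <- function(l_um, sigma_um, a) {
  if (a <= 0) return(0)
  if (l_um <= 0) return(min(1, a))
  f <- function(d) pmin(1, a * exp(-d^2 / (2 * sigma_um^2))) *
    2 * (l_um - d) / l_um^2
  stats::integrate(f, 0, l_um, rel.tol = 1e-8)$value
}

# Per-rule increment factors that conserve the expected in-degree x weight
# product when populations and slice thickness shrink by `scale`.  Intra-area
# probabilities never clip (amplitudes <= 1 at zero distance), so a single
# kernel-mass ratio per presynaptic class suffices; inter-area projections
# clip at probability 1, so their factor is evaluated at each projection's
# reference amplitude.
.scale_increment_factors <- function(scale, wiring, z_full_um = 15000) {
  sigma_um <- wiring$sigma_um
  z_s <- z_full_um * scale
  f <- function(sigma)
    z_kernel_mean(z_full_um, sigma) / (scale * z_kernel_mean(z_s, sigma))
  gains <- wiring$inter_gain
  inter <- gains
  inter[] <- 1
  s_int <- sigma_um[["inter"]]
  for (a in rownames(gains)) for (b in colnames(gains)) {
    if (gains[a, b] > 0)
      inter[a, b] <- .clipped_kernel_mean(z_full_um, s_int, gains[a, b]) /
        (scale * .clipped_kernel_mean(z_s, s_int, gains[a, b]))
  }
  list(intra_exc = f(sigma_um[["intra_exc"]]),
       intra_inh = f(sigma_um[["intra_inh"]]),
       inter = inter)
}

.annular_polygon <- function(r_in, r_out, a0, a1, n = 60) {
  th1 <- seq(a0, a1, length.out = n)
  th2 <- rev(th1)
  data.frame(x = c(r_out * cos(th1), r_in * cos(th2)),
             y = c(r_out * sin(th1), r_in * sin(th2)))
}

.polygon_area <- function(p) {
  x <- p$x; y <- p$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Parametric slice geometry
#'
#' The hand-traced anatomical slice of the original preparation is replaced
#' by a parametric geometry: four nested curved bands (annular sectors, in
#' micrometres) for EC, DG, CA3 and CA1, each split into a principal-cell
#' stratum (pyramidale/granulosum, inner band) hosting excitatory cells and
#' an oriens-like outer band hosting interneurons.  The slice extends 15 mm
#' along z.  All connectivity rules depend only on distances, so any geometry
#' of comparable spatial extent preserves the model class.
#'
#' @param z_extent_um slice thickness along z (default 15000).
#' @return a list of class `slice_geometry`: per-region polygons (`$regions`,
#'   each with `exc` and `inh` data frames of vertices in micrometres) and
#'   `z_extent_um`.
#' @export
slice_geometry <- function(z_extent_um = 15000) {
  d2r <- pi / 180
  regions <- list(
    EC  = list(exc = .annular_polygon(4200, 4600, -100 * d2r, 20 * d2r),
               inh = .annular_polygon(4600, 5000, -100 * d2r, 20 * d2r)),
    DG  = list(exc = .annular_polygon(1200, 1600, 40 * d2r, 160 * d2r),
               inh = .annular_polygon(1600, 2000, 40 * d2r, 160 * d2r)),
    CA3 = list(exc = .annular_polygon(2000, 2400, 160 * d2r, 270 * d2r),
               inh = .annular_polygon(2400, 2800, 160 * d2r, 270 * d2r)),
    CA1 = list(exc = .annular_polygon(3000, 3400, 20 * d2r, 140 * d2r),
               inh = .annular_polygon(3400, 3800, 20 * d2r, 140 * d2r)))
  structure(list(regions = regions, z_extent_um = z_extent_um),
            class = "slice_geometry")
}

.uniform_in_polygon <- function(n, poly) {
  xr <- range(poly$x); yr <- range(poly$y)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * n, 256L)
    x <- runif(m, xr[1], xr[2]); y <- runif(m, yr[1], yr[2])
    keep <- points_in_polygon_cpp(x, y, poly$x, poly$y)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Blue-noise neuron placement with Lloyd relaxation
#'
#' Places each population inside its stratum polygon: initial positions are
#' drawn from a Poisson-disk (blue-noise) distribution, then refined towards
#' a centroidal Voronoi configuration by Lloyd relaxation (against a dense
#' uniform sample of the polygon), capped at `lloyd_iter` iterations with an
#' early stop when the relative energy change drops below `lloyd_tol`.  The
#' third coordinate is drawn uniformly over the slice thickness.
#'
#' @param geometry a [slice_geometry()].
#' @param counts data frame with columns `area`, `n_exc`, `n_inh` (defaults
#'   to [wiring_defaults()] sizes).
#' @param seed integer seed.
#' @param lloyd_iter maximum Lloyd iterations (default 1000).
#' @param lloyd_tol relative energy-change early-stop threshold (default 1e-6).
#' @return data frame of class `population_layout`: `neuron`, `area`,
#'   `cell` (`"exc"`/`"inh"`), `x`, `y`, `z` (micrometres).
#' @export
place_neurons <- function(geometry = slice_geometry(),
                          counts = wiring_defaults()$sizes,
                          seed = NULL, lloyd_iter = 1000, lloyd_tol = 1e-6) {
  stopifnot(inherits(geometry, "slice_geometry"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    area <- as.character(counts$area[i])
    reg <- geometry$regions[[area]]
    if (is.null(reg)) .stopf("geometry has no region '%s'", area)
    for (cl in c("exc", "inh")) {
      n <- if (cl == "exc") counts$n_exc[i] else counts$n_inh[i]
      if (n < 1) next
      poly <- reg[[cl]]
      a <- .polygon_area(poly)
      if (a / n < 16) # < 4 um spacing: denser than somata allow
        .stopf("region %s/%s too small for %d neurons", area, cl, n)
      r <- 0.55 * sqrt(a / n)
      pts <- poisson_disk_cpp(n, r, poly$x, poly$y, max_attempts = 400L * n)
      while (nrow(pts) < n && r > 1) {     # relax the disk radius if saturated
        r <- 0.8 * r
        pts <- poisson_disk_cpp(n, r, poly$x, poly$y, max_attempts = 400L * n)
      }
      if (nrow(pts) < n) .stopf("placement failed for %s/%s", area, cl)
      samples <- .uniform_in_polygon(min(20L * n, 200000L), poly)
      rel <- lloyd_relax_cpp(pts, samples, lloyd_iter, lloyd_tol)
      rows[[length(rows) + 1L]] <-
        data.frame(area = area, cell = cl,
                   x = rel$sites[, 1], y = rel$sites[, 2],
                   z = runif(n, 0, geometry$z_extent_um))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(neuron = seq_len(nrow(out)), out)
  class(out) <- c("population_layout", "data.frame")
  out
}

#' Intra-area wiring
#'
#' Draws one independent Bernoulli edge per ordered neuron pair within an
#' area, with probability \eqn{p = A_{intra}\exp(-D^2 / 2\sigma^2)} where `D`
#' is the full 3D Euclidean distance; no self-connections.
#'
#' @param pre,post data frames with columns `x`, `y`, `z` (micrometres) for
#'   the pre- and postsynaptic populations; pass the same object for
#'   recurrent wiring within one population.
#' @param a_intra maximum connection probability at zero distance.
#' @param sigma_um kernel width (2500 for excitatory, 350 for inhibitory
#'   presynaptic populations by default).
#' @param seed optional integer seed.
#' @return data frame with `pre` and `post` indices (1-based within each
#'   population).
#' @export
connect_intra <- function(pre, post, a_intra, sigma_um, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (a_intra < 0 || a_intra > 1) .stopf("a_intra must be in [0, 1]")
  if (a_intra == 0 || nrow(pre) == 0 || nrow(post) == 0)
    return(data.frame(pre = integer(0), post = integer(0)))
  same <- identical(rownames(pre), rownames(post)) && nrow(pre) == nrow(post) &&
    all(pre$x == post$x & pre$y == post$y & pre$z == post$z)
  ed <- connect_pairs_cpp(as.matrix(pre[, c("x", "y", "z")]),
                          as.matrix(post[, c("x", "y", "z")]),
                          a_intra, sigma_um, same, FALSE, FALSE)
  data.frame(pre = ed$pre, post = ed$post)
}

#' Inter-area wiring
#'
#' Projections between areas originate from excitatory cells only and target
#' both classes; the connection probability depends only on the z-distance,
#' \eqn{p = \min(1, A_{inter}\exp(-D_z^2 / 2\sigma^2))}.
#'
#' @param source data frame (`x`,`y`,`z`) of the source excitatory population.
#' @param target data frame (`x`,`y`,`z`) of the target population.
#' @param a_inter connection-strength amplitude (may exceed 1; probability is
#'   clipped).
#' @param sigma_um kernel width (default 1000).
#' @param source_class class of the source population; inhibitory sources are
#'   rejected.
#' @param seed optional integer seed.
#' @return data frame with `pre` and `post` indices.
#' @export
connect_inter <- function(source, target, a_inter, sigma_um = 1000,
                          source_class = "exc", seed = NULL) {
  if (!identical(source_class, "exc"))
    .stopf("inter-area projections must originate from an excitatory population")
  if (!is.null(seed)) set.seed(seed)
  if (a_inter < 0) .stopf("a_inter must be >= 0")
  if (a_inter == 0 || nrow(source) == 0 || nrow(target) == 0)
    return(data.frame(pre = integer(0), post = integer(0)))
  ed <- connect_pairs_cpp(as.matrix(source[, c("x", "y", "z")]),
                          as.matrix(target[, c("x", "y", "z")]),
                          a_inter, sigma_um, FALSE, TRUE, TRUE)
  data.frame(pre = ed$pre, post = ed$post)
}

#' Build the full connectivity graph
#'
#' Assembles the directed synaptic graph of the four-area network from a
#' neuron layout: intra-area wiring per ordered class pair (Gaussian distance
#' kernel, per-pair increments) and excitatory inter-area projections
#' (z-distance kernel, per-projection increments and gains).  Increments can
#' be compensated by `1/scale` when populations are subsampled, which
#' conserves the mean synaptic conductance received per neuron.
#'
#' @param layout a [place_neurons()] layout.
#' @param wiring wiring constants, as [wiring_defaults()]; `inter_gain`
#'   entries may be overridden (e.g. by the tuning procedure).
#' @param increment_factors multipliers applied to the conductance
#'   increments of each wiring rule: scalars `intra_exc` and `intra_inh`
#'   plus an `inter` matrix (source x target area).  For scaled-down
#'   networks these are kernel-mass ratios, which conserve the expected
#'   in-degree-times-weight of every rule (the drive a neuron receives per
#'   presynaptic population spike).
#' @param seed optional integer seed.
#' @return object of class `connectivity_graph`: data frame `edges` with
#'   global `pre`, `post`, `weight_ps`, `kind` (`"E"`/`"I"`) and `rule`
#'   (`"intra"`/`"inter"`), plus the layout.
#' @export
build_topology <- function(layout, wiring = wiring_defaults(),
                           increment_factors = NULL, seed = NULL) {
  if (is.null(increment_factors)) {
    ones <- wiring$inter_gain; ones[] <- 1
    increment_factors <- list(intra_exc = 1, intra_inh = 1, inter = ones)
  }
  if (!is.null(seed)) set.seed(seed)
  areas <- rownames(wiring$intra_prob)
  idx <- function(a, cl) which(layout$area == a & layout$cell == cl)
  pieces <- list()
  for (a in areas) {
    for (pair in c("EE", "EI", "IE", "II")) {
      p <- wiring$intra_prob[a, pair]
      if (p <= 0) next
      pre_cl <- if (substr(pair, 1, 1) == "E") "exc" else "inh"
      post_cl <- if (substr(pair, 2, 2) == "E") "exc" else "inh"
      ip <- idx(a, pre_cl); io <- idx(a, post_cl)
      if (!length(ip) || !length(io)) next
      sig <- if (pre_cl == "exc") wiring$sigma_um[["intra_exc"]]
             else wiring$sigma_um[["intra_inh"]]
      ed <- connect_intra(layout[ip, ], layout[io, ], p, sig)
      if (!nrow(ed)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        pre = ip[ed$pre], post = io[ed$post],
        weight_ps = wiring$intra_increment_ps[a, pair] *
          increment_factors[[if (pre_cl == "exc") "intra_exc" else "intra_inh"]],
        kind = if (pre_cl == "exc") "E" else "I", rule = "intra")
    }
  }
  for (a in areas) for (b in areas) {
    gain <- wiring$inter_gain[a, b]
    if (a == b || gain <= 0) next
    ip <- idx(a, "exc")
    for (post_cl in c("exc", "inh")) {
      io <- idx(b, post_cl)
      if (!length(ip) || !length(io)) next
      ed <- connect_inter(layout[ip, ], layout[io, ], gain,
                          wiring$sigma_um[["inter"]])
      if (!nrow(ed)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        pre = ip[ed$pre], post = io[ed$post],
        weight_ps = wiring$inter_increment_ps[a, b] *
          increment_factors$inter[a, b],
        kind = "E", rule = "inter")
    }
  }
  edges <- if (length(pieces)) do.call(rbind, pieces)
           else data.frame(pre = integer(0), post = integer(0),
                           weight_ps = numeric(0), kind = character(0),
                           rule = character(0))
  structure(list(edges = edges, layout = layout, wiring = wiring,
                 increment_factors = increment_factors),
            class = "connectivity_graph")
}
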