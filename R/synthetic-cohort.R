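#' Specification for the cohort-connectivity generator
#'
#' Describes a cohort of subjects, each with a symmetric connectivity
#' matrix whose entries are logistic squashings of independent latent
#' Gaussian edge scores, plus scalar target indexes built as linear
#' combinations of planted edges with additive Gaussian noise. This is
#' the stand-in for a real cohort of per-subject PLV matrices with
#' behavioral or ERP indexes: the planted edges define exactly which
#' connectivity features carry signal, so prediction methods can be
#' validated by parameter recovery.
#'
#' @param n_subjects cohort size (>= 3). Defaults of interest: 46 for
#'   behavioral targets, 40 for neural targets.
#' @param region_labels character vector of region labels.
#' @param planted_edges `NULL` or data frame with columns `region_a`,
#'   `region_b`, `target`, `beta`: each row adds
#'   `beta * z(edge value across subjects)` to the named target.
#' @param noise_sd sd of the Gaussian noise added to every target. With
#'   one planted edge of `beta = 1`, the population correlation between
#'   the edge and the target is `1 / sqrt(1 + noise_sd^2)`.
#' @param target_names names of the target columns to generate.
#' @param backbone `"none"` for exchangeable edges, or `"small_world"`
#'   to shift the latent edge means up along a ring lattice (cyclic
#'   neighbor distance `<= backbone_k`) and down elsewhere, giving every
#'   subject's matrix the clustered, short-path topology of cortical
#'   connectivity once thresholded.
#' @param backbone_k lattice half-width (neighbors per side).
#' @param backbone_strength latent mean shift magnitude.
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 46,
                        region_labels,
                        planted_edges = NULL,
                        noise_sd = 1,
                        target_names = c("delta_global_rt",
                                         "delta_global_acc",
                                         "delta_global_ies"),
                        backbone = c("none", "small_world"),
                        backbone_k = 2L,
                        backbone_strength = 1,
                        seed = 1L) {
  backbone <- match.arg(backbone)
  region_labels <- as.character(region_labels)
  stopifnot(n_subjects >= 3, length(region_labels) >= 2,
            !anyDuplicated(region_labels), noise_sd >= 0,
            length(target_names) >= 1)
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("region_a", "region_b", "target", "beta") %in%
                    names(planted_edges)))
    if (any(planted_edges$region_a == planted_edges$region_b))
      stop("planted edge on the diagonal (region_a == region_b)")
    bad <- !(planted_edges$region_a %in% region_labels &
               planted_edges$region_b %in% region_labels)
    if (any(bad))
      stop("planted edge references unknown region(s): ",
           paste(unique(c(planted_edges$region_a[bad],
                          planted_edges$region_b[bad])), collapse = ", "))
    if (!all(planted_edges$target %in% target_names))
      stop("planted edge targets an unknown target name")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 region_labels = region_labels,
                 planted_edges = planted_edges,
                 noise_sd = noise_sd,
                 target_names = as.character(target_names),
                 backbone = backbone,
                 backbone_k = as.integer(backbone_k),
                 backbone_strength = backbone_strength,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of connectivity matrices with planted effects
#'
#' Per subject, draws independent latent standard-normal scores for
#' every region pair, maps them through `plogis` to obtain symmetric
#' matrices with off-diagonal entries in `(0, 1)` and zero diagonal,
#' and builds each target as the sum of `beta * z(edge)` over its
#' planted edges (z-scoring across the cohort) plus Gaussian noise.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `matrices` (list of
#'   [connectivity_matrix()], one per subject) and `targets` (data frame
#'   with column `subject` plus one column per target name).
#' @export
simulate_cohort_connectivity <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labs <- spec$region_labels
  n <- length(labs)
  ns <- spec$n_subjects
  ut <- which(upper.tri(matrix(0, n, n)))
  latent <- matrix(stats::rnorm(ns * length(ut)), ns, length(ut))
  if (spec$backbone == "small_world") {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    circ <- pmin(abs(ij[, 1] - ij[, 2]), n - abs(ij[, 1] - ij[, 2]))
    mu <- ifelse(circ <= spec$backbone_k,
                 spec$backbone_strength, -spec$backbone_strength)
    latent <- sweep(latent, 2, mu, "+")
  }
  edge_vals <- stats::plogis(latent)           # subjects x edges, in (0,1)
  matrices <- lapply(seq_len(ns), function(s) {
    m <- matrix(0, n, n)
    m[ut] <- edge_vals[s, ]
    m <- m + t(m)
    connectivity_matrix(m, labs)
  })
  subj <- sprintf("S%03d", seq_len(ns))
  targets <- data.frame(subject = subj)
  # column-major upper-triangle indexing: edge (i, j), i < j
  ut_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (tn in spec$target_names) {
    y <- numeric(ns)
    if (!is.null(spec$planted_edges)) {
      pe <- spec$planted_edges[spec$planted_edges$target == tn, , drop = FALSE]
      for (k in seq_len(nrow(pe))) {
        a <- match(pe$region_a[k], labs); b <- match(pe$region_b[k], labs)
        i <- min(a, b); j <- max(a, b)
        col <- which(ut_ij[, 1] == i & ut_ij[, 2] == j)
        y <- y + pe$beta[k] * as.numeric(scale(edge_vals[, col]))
      }
    }
    targets[[tn]] <- y + stats::rnorm(ns, 0, spec$noise_sd)
  }
  list(matrices = matrices, targets = targets)
}
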