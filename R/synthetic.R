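#' Configure the sib-family simulator
#'
#' The simulator emulates the structure the selection indices exercise in
#' real breeding panels: block-structured genomic relatedness (full-sib
#' families sharing two parents) and multiple genetically correlated
#' traits. Defaults describe a desk-scale panel: 5 families of 10
#' full-sibs (n = 50), 500 biallelic markers with founder allele
#' frequencies away from the boundaries, four traits with moderate
#' (0.3) pairwise genetic correlation and a signal fraction of 0.7 —
#' BLUEs from replicated trials are good but not noise-free estimates of
#' genetic merit.
#'
#' @param n_families number of full-sib families.
#' @param family_size offspring per family; `n = n_families * family_size`.
#' @param p_markers number of biallelic markers (dosages 0/1/2).
#' @param allele_freq_range interval in (0, 1) for founder allele
#'   frequencies; keeping it off the boundaries avoids monomorphic
#'   markers.
#' @param trait_corr `p0 x p0` genetic correlation matrix (symmetric,
#'   positive semidefinite, unit diagonal).
#' @param h2 per-trait fraction of trait variance that is genetic
#'   (marker-driven), in (0, 1]; recycled across traits.
#' @param directions per-trait improvement direction flags.
#' @param seed integer master seed; every draw in both simulation stages
#'   derives deterministically from it.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_families = 5L, family_size = 10L,
                              p_markers = 500L,
                              allele_freq_range = c(0.1, 0.9),
                              trait_corr = default_trait_corr(4L),
                              h2 = 0.7,
                              directions = NULL,
                              seed = 1L) {
  n_families <- as.integer(n_families); family_size <- as.integer(family_size)
  p_markers <- as.integer(p_markers)
  if (n_families < 1L || family_size < 1L || n_families * family_size < 2L)
    mts_stop("invalid_config", "need n_families x family_size >= 2")
  if (p_markers < 1L) mts_stop("invalid_config", "need p_markers >= 1")
  if (length(allele_freq_range) != 2L || allele_freq_range[1] <= 0 ||
      allele_freq_range[2] >= 1 || diff(allele_freq_range) < 0)
    mts_stop("invalid_config", "allele_freq_range must be an interval inside (0, 1)")
  trait_corr <- as.matrix(trait_corr)
  p0 <- nrow(trait_corr)
  if (ncol(trait_corr) != p0 || max(abs(trait_corr - t(trait_corr))) > 1e-8 ||
      any(abs(diag(trait_corr) - 1) > 1e-8))
    mts_stop("non_psd_correlation", "trait_corr must be symmetric with unit diagonal")
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    mts_stop("non_psd_correlation", "trait_corr is not positive semidefinite")
  h2 <- rep_len(as.numeric(h2), p0)
  if (any(h2 <= 0 | h2 > 1))
    mts_stop("invalid_config", "h2 must lie in (0, 1]")
  if (is.null(directions)) directions <- rep("higher_is_better", p0)
  check_directions(directions, p0)
  structure(list(n_families = n_families, family_size = family_size,
                 p_markers = p_markers, allele_freq_range = allele_freq_range,
                 trait_corr = trait_corr, h2 = h2, directions = directions,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

default_trait_corr <- function(p0, rho = 0.3) {
  m <- matrix(rho, p0, p0)
  diag(m) <- 1
  m
}

# stage-specific sub-seed derived from the master seed, kept under 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000000L) * 10L + stage
}

#' Simulate full-sib family marker dosages
#'
#' For every marker a founder allele frequency is drawn uniformly from
#' the configured range. Each family gets two parents with dosages drawn
#' as Binomial(2, freq); offspring receive one allele from each parent by
#' Mendelian sampling (transmit the alternative allele with probability
#' dosage/2). Shared parents make within-family relatedness exceed
#' between-family relatedness in the derived G. Markers that come out
#' monomorphic across the offspring are redrawn (new founder frequency
#' and parental genotypes) so the matrix always standardizes cleanly.
#'
#' @param config a [simulation_config()].
#' @return A list: `markers` (a [marker_matrix()]) and `family` (integer
#'   family label per genotype).
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 1L))
  nf <- config$n_families; fs <- config$family_size
  n <- nf * fs; p <- config$p_markers
  lo <- config$allele_freq_range[1]; hi <- config$allele_freq_range[2]
  draw_block <- function(p_block) {
    freq <- runif(p_block, lo, hi)
    dos <- matrix(0L, n, p_block)
    for (f in seq_len(nf)) {
      par1 <- rbinom(p_block, 2L, freq)
      par2 <- rbinom(p_block, 2L, freq)
      rows <- ((f - 1L) * fs + 1L):(f * fs)
      for (i in rows) {
        a1 <- rbinom(p_block, 1L, par1 / 2)
        a2 <- rbinom(p_block, 1L, par2 / 2)
        dos[i, ] <- a1 + a2
      }
    }
    dos
  }
  dosages <- draw_block(p)
  for (attempt in seq_len(100L)) {
    mono <- which(apply(dosages, 2L, function(col) length(unique(col)) == 1L))
    if (!length(mono)) break
    dosages[, mono] <- draw_block(length(mono))
  }
  if (length(mono <- which(apply(dosages, 2L, function(col)
    length(unique(col)) == 1L))))
    message(sprintf("note: %d marker(s) still monomorphic after redraws", length(mono)))
  ids <- sprintf("F%02d_%03d", rep(seq_len(nf), each = fs),
                 rep(seq_len(fs), times = nf))
  list(markers = marker_matrix(dosages, genotype_ids = ids,
                               marker_names = sprintf("M%04d", seq_len(p))),
       family = rep(seq_len(nf), each = fs))
}

#' Simulate correlated multi-trait BLUEs on top of marker data
#'
#' Per-trait genetic values are linear in the centred markers with random
#' effects drawn to carry the target inter-trait correlation (effect rows
#' are i.i.d. multivariate normal with covariance `trait_corr`). Each
#' genetic value is rescaled to unit variance and mixed with independent
#' normal noise as `sqrt(h2) * genetic + sqrt(1 - h2) * noise`, so `h2`
#' is the fraction of trait variance carried by the markers. The output
#' plays the role of a BLUE table: trait values that reflect genetic
#' merit plus residual estimation noise.
#'
#' @param markers a [marker_matrix()] (typically from
#'   [simulate_markers()]).
#' @param config the same [simulation_config()].
#' @return A [trait_table()]; the pure genetic values are attached as
#'   attribute `"genetic_values"` for calibration checks.
#' @export
simulate_traits <- function(markers, config) {
  stopifnot(inherits(markers, "marker_matrix"),
            inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 2L))
  p0 <- nrow(config$trait_corr)
  W <- scale(markers$dosages)            # centred, unit-SD columns
  W[, !is.finite(colSums(W))] <- 0       # guard: monomorphic column -> no signal
  p <- ncol(W); n <- nrow(W)
  L <- chol_psd(config$trait_corr)
  effects <- matrix(rnorm(p * p0), p, p0) %*% L
  g <- W %*% effects
  g <- scale(g)                          # unit-variance genetic values
  noise <- matrix(rnorm(n * p0), n, p0)
  raw <- sweep(g, 2L, sqrt(config$h2), "*") +
    sweep(noise, 2L, sqrt(1 - config$h2), "*")
  attr(raw, "scaled:center") <- NULL
  attr(raw, "scaled:scale") <- NULL
  attr(g, "scaled:center") <- NULL
  attr(g, "scaled:scale") <- NULL
  tt <- trait_table(raw, directions = config$directions,
                    genotype_ids = markers$genotype_ids,
                    trait_names = sprintf("T%d", seq_len(p0)))
  attr(tt, "genetic_values") <- g
  tt
}

# Cholesky tolerant of PSD-but-singular correlation targets
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(vals), nrow = length(vals)))
}

#' Simulate a complete dataset: markers, traits and family labels
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_dataset` list: `markers`, `traits`, `family`,
#'   `config`. Identical `(config, seed)` pairs reproduce the dataset
#'   exactly.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  mk <- simulate_markers(config)
  traits <- simulate_traits(mk$markers, config)
  structure(list(markers = mk$markers, traits = traits,
                 family = mk$family, config = config),
            class = "synthetic_dataset")
}
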