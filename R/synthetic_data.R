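#' Configuration for synthetic NMR shift datasets
#'
#' The generator emulates the shape of predicted-shift inputs for drug-like
#' compounds: 5-40 carbon shifts per compound uniform on [0, 240) ppm, 0-6
#' nitrogen shifts on [0, 600) ppm with a 20% chance of a nitrogen-free
#' compound, and class-imbalanced labels (36% inhibitors by default, the
#' CYP3A4 training fraction; use 0.26 for the CYP2D6 composition). Class
#' signal is planted as ppm windows in which compounds receive extra
#' Poisson-distributed shifts at a class-specific rate. The spectra are
#' statistically, not chemically, realistic.
#'
#' @param n_compounds Number of compounds (default 602, the training-set
#'   size the models were developed on).
#' @param positive_fraction Probability a compound is an inhibitor.
#' @param carbon_count_range Inclusive range of carbon shifts per compound.
#' @param nitrogen_count_max Maximum nitrogen shifts per compound.
#' @param p_nitrogen_free Probability of zero nitrogen shifts.
#' @param carbon_range,nitrogen_range Background ppm supports.
#' @param planted_windows List of windows, each
#'   \code{list(nucleus, lo, hi, rate_pos, rate_neg)}: extra shifts are
#'   drawn per compound as Poisson(rate of its class), placed uniformly in
#'   [lo, hi).
#' @param seed Integer seed.
#' @return List of class \code{"spectra_sim_config"}.
#' @export
spectra_sim_config <- function(n_compounds = 602L, positive_fraction = 0.36,
                               carbon_count_range = c(5L, 40L),
                               nitrogen_count_max = 6L,
                               p_nitrogen_free = 0.2,
                               carbon_range = c(0, 240),
                               nitrogen_range = c(0, 600),
                               planted_windows = list(), seed = 1L) {
  stopifnot(n_compounds >= 2L, positive_fraction > 0, positive_fraction < 1,
            carbon_count_range[1] >= 0, diff(carbon_count_range) >= 0,
            p_nitrogen_free >= 0, p_nitrogen_free <= 1,
            diff(carbon_range) > 0, diff(nitrogen_range) > 0)
  for (w in planted_windows) {
    rng <- if (w$nucleus == "C13") carbon_range else nitrogen_range
    if (w$lo < rng[1] || w$hi > rng[2] || w$lo >= w$hi) {
      stop("planted window outside the background range (or degenerate)")
    }
    if (w$rate_pos < 0 || w$rate_neg < 0) stop("planted rates must be >= 0")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 positive_fraction = positive_fraction,
                 carbon_count_range = as.integer(carbon_count_range),
                 nitrogen_count_max = as.integer(nitrogen_count_max),
                 p_nitrogen_free = p_nitrogen_free,
                 carbon_range = carbon_range, nitrogen_range = nitrogen_range,
                 planted_windows = planted_windows, seed = as.integer(seed)),
            class = "spectra_sim_config")
}

#' Generate a synthetic shift-list dataset
#'
#' @param config A [spectra_sim_config()].
#' @return List with \code{records} (shift records, one per compound per
#'   occupied nucleus), \code{labels} (named 0/1 vector), and
#'   \code{ground_truth} (planted windows and, per compound, the planted
#'   shift values themselves, for recovery checks).
#' @export
generate_spectra_dataset <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  with_seed(config$seed, {
    n <- config$n_compounds
    ids <- sprintf("cmp%04d", seq_len(n))
    y <- stats::setNames(stats::rbinom(n, 1L, config$positive_fraction), ids)

    ccr <- config$carbon_count_range
    n_c <- sample(seq.int(ccr[1], ccr[2]), n, replace = TRUE)
    n_probs <- c(config$p_nitrogen_free,
                 rep((1 - config$p_nitrogen_free) / config$nitrogen_count_max,
                     config$nitrogen_count_max))
    n_n <- sample(0:config$nitrogen_count_max, n, replace = TRUE,
                  prob = n_probs)

    planted_shifts <- vector("list", n)
    records <- list()
    for (i in seq_len(n)) {
      c_shifts <- stats::runif(n_c[i], config$carbon_range[1],
                               config$carbon_range[2])
      n_shifts <- stats::runif(n_n[i], config$nitrogen_range[1],
                               config$nitrogen_range[2])
      planted <- list()
      for (w in seq_along(config$planted_windows)) {
        win <- config$planted_windows[[w]]
        rate <- if (y[i] == 1L) win$rate_pos else win$rate_neg
        k <- stats::rpois(1L, rate)
        extra <- stats::runif(k, win$lo, win$hi)
        planted[[w]] <- extra
        if (win$nucleus == "C13") c_shifts <- c(c_shifts, extra)
        else n_shifts <- c(n_shifts, extra)
      }
      planted_shifts[[i]] <- planted
      records[[length(records) + 1L]] <- shift_record(ids[i], "C13", c_shifts)
      if (length(n_shifts)) {
        records[[length(records) + 1L]] <- shift_record(ids[i], "N15", n_shifts)
      }
    }
    list(records = records, labels = y,
         ground_truth = list(planted_windows = config$planted_windows,
                             planted_shifts = stats::setNames(planted_shifts, ids),
                             config = config))
  })
}

#' Configuration for synthetic descriptor tables
#'
#' Emulates a numeric molecular-descriptor table (777 columns by default,
#' the size of a full 2D-descriptor battery) with planted class signal:
#' informative descriptors are standard normal for non-inhibitors and mean-
#' shifted by \code{effect_size} (in within-class standard deviations) for
#' inhibitors. Informative descriptors can be grouped into correlated
#' blocks; constant columns can be appended to exercise the entropy filter.
#'
#' @param n_compounds Default 602.
#' @param n_descriptors Total descriptors (default 777).
#' @param n_informative Number of class-informative descriptors.
#' @param effect_size Standardized mean difference per informative
#'   descriptor (default 1).
#' @param n_blocks Number of informative blocks; descriptors within a block
#'   share a latent factor (default: one block per informative descriptor,
#'   i.e. uncorrelated).
#' @param block_rho Within-block correlation (default 0).
#' @param positive_fraction Inhibitor probability (default 0.36).
#' @param n_constant Constant (zero-entropy) columns appended.
#' @param seed Integer seed.
#' @return List of class \code{"descriptor_sim_config"}.
#' @export
descriptor_sim_config <- function(n_compounds = 602L, n_descriptors = 777L,
                                  n_informative = 25L, effect_size = 1,
                                  n_blocks = n_informative, block_rho = 0,
                                  positive_fraction = 0.36, n_constant = 0L,
                                  seed = 1L) {
  stopifnot(n_informative <= n_descriptors, n_constant < n_descriptors,
            n_blocks >= 1L, n_blocks <= max(n_informative, 1L),
            block_rho >= 0, block_rho < 1,
            positive_fraction > 0, positive_fraction < 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, n_blocks = as.integer(n_blocks),
                 block_rho = block_rho,
                 positive_fraction = positive_fraction,
                 n_constant = as.integer(n_constant), seed = as.integer(seed)),
            class = "descriptor_sim_config")
}

#' Generate a synthetic descriptor table
#'
#' @param config A [descriptor_sim_config()].
#' @return List with \code{X} (matrix, columns \code{D0001}...),
#'   \code{labels} (named 0/1), and \code{ground_truth} (informative
#'   descriptor names, their block assignment, constant column names).
#' @export
generate_descriptor_dataset <- function(config) {
  stopifnot(inherits(config, "descriptor_sim_config"))
  with_seed(config$seed, {
    n <- config$n_compounds; p <- config$n_descriptors
    ids <- sprintf("cmp%04d", seq_len(n))
    names_all <- sprintf("D%04d", seq_len(p))
    y <- stats::setNames(stats::rbinom(n, 1L, config$positive_fraction), ids)

    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(ids, names_all))
    ni <- config$n_informative
    informative <- names_all[seq_len(ni)]
    block_of <- integer(0)
    if (ni > 0L) {
      block_of <- rep_len(seq_len(config$n_blocks), ni)
      if (config$block_rho > 0) {
        factors <- matrix(stats::rnorm(n * config$n_blocks), n)
        r <- sqrt(config$block_rho)
        for (j in seq_len(ni)) {
          X[, j] <- r * factors[, block_of[j]] + sqrt(1 - config$block_rho) * X[, j]
        }
      }
      X[, seq_len(ni)] <- X[, seq_len(ni), drop = FALSE] +
        config$effect_size * matrix(y, n, ni)
    }
    constant <- character(0)
    if (config$n_constant > 0L) {
      constant <- names_all[(p - config$n_constant + 1L):p]
      X[, constant] <- 1
    }
    list(X = X, labels = y,
         ground_truth = list(informative = informative,
                             block = stats::setNames(block_of, informative),
                             constant = constant, config = config))
  })
}
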