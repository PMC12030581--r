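# Synthetic release datasets with known kinetic ground truth, shaped like
# the 39-sample literature compilation: 6-37 points per curve, time scales
# from hours to weeks, release 0-100 percent.

# The seven release time-scale bins (hours) spanned by the compiled
# literature curves.
time_scale_bins <- function() {
  list(c(0, 10), c(10, 20), c(20, 40), c(40, 100), c(100, 200),
       c(200, 400), c(400, 1000))
}

#' Configuration for the synthetic dataset generator
#'
#' @param n_samples number of samples (default 39, the size of the
#'   literature compilation the generator emulates).
#' @param points_range min/max observations per curve (default `c(6, 37)`).
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise, in release percent (default 2).
#' @param weibull_fraction fraction of samples whose true kinetics are
#'   Weibull (the rest are Korsmeyer-Peppas; default 0.5).
#' @param biologic_fraction fraction of samples assigned a protein drug
#'   with no structure and hence missing descriptors (default 0, the
#'   worked fixture exercises this path instead).
#' @param time_spacing `"log"` (dense early, sparse late — the usual
#'   release sampling design) or `"linear"`.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 39L, points_range = c(6L, 37L),
                             noise_sd = 2, weibull_fraction = 0.5,
                             biologic_fraction = 0,
                             time_spacing = c("log", "linear"), seed = 1L) {
  time_spacing <- match.arg(time_spacing)
  if (points_range[2] < points_range[1]) {
    stop("points_range max < min", call. = FALSE)
  }
  stopifnot(n_samples >= 1L, points_range[1] >= 3L, noise_sd >= 0,
            weibull_fraction >= 0, weibull_fraction <= 1,
            biologic_fraction >= 0, biologic_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 points_range = as.integer(points_range),
                 noise_sd = noise_sd,
                 weibull_fraction = weibull_fraction,
                 biologic_fraction = biologic_fraction,
                 time_spacing = time_spacing,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic release dataset with known ground truth
#'
#' Each sample gets: carrier features drawn from plausible PLGA ranges
#' (molecular weight 10-120 kDa, PDI 0.05-0.4, particle size 80-400 nm,
#' zeta potential -40 to +10 mV, lactide fraction 0.5-0.9, encapsulation
#' efficiency 40-95 percent); a real drug drawn from the offline structure
#' cache; a release time scale drawn from the seven canonical bins; and a
#' release curve simulated from a randomly parameterized Korsmeyer-Peppas
#' or Weibull truth model, times 100, plus i.i.d. Gaussian noise (clipped
#' below at 0). Weibull truths use tau between 15 and 50 percent of the
#' observation horizon and beta in 0.6-1.4; K-P truths use an exponent in
#' 0.3-0.9 with the rate constant set so the final release lands between
#' 60 and 95 percent. K-P curves may legitimately exceed 100 percent at
#' late times since the power law is uncapped.
#'
#' @param config a [generator_config()].
#' @return list with `dataset` (a `release_dataset`) and `truth`
#'   (data.frame: `sample_id`, `model`, `p1`, `p2`, `noise_sd`; `p1`/`p2`
#'   are k/n for K-P truths and tau/beta for Weibull truths).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(derive_seed(config$seed, "generate"), {
    n <- config$n_samples
    cache <- drug_structure_cache()
    small <- cache[cache$kind == "small_molecule", ]
    bio <- cache[cache$kind == "biologic", ]
    bins <- time_scale_bins()

    samples <- data.frame(
      sample_id = seq_len(n),
      drug_name = NA_character_, smiles = NA_character_,
      polymer_mw = runif(n, 10, 120),
      pdi = runif(n, 0.05, 0.4),
      particle_size = runif(n, 80, 400),
      zeta_potential = runif(n, -40, 10),
      monomer_ratio = runif(n, 0.5, 0.9),
      encapsulation_efficiency = runif(n, 40, 95),
      source = "synthetic", stringsAsFactors = FALSE)
    for (d in descriptor_features()) samples[[d]] <- NA_real_

    is_bio <- runif(n) < config$biologic_fraction
    ns_small <- sum(!is_bio)
    samples$drug_name[!is_bio] <-
      small$drug_name[sample.int(nrow(small), ns_small, replace = TRUE)]
    samples$smiles[!is_bio] <-
      small$smiles[match(samples$drug_name[!is_bio], small$drug_name)]
    if (any(is_bio)) {
      samples$drug_name[is_bio] <-
        bio$drug_name[sample.int(nrow(bio), sum(is_bio), replace = TRUE)]
    }

    is_weibull <- runif(n) < config$weibull_fraction
    obs <- vector("list", n)
    truth <- data.frame(sample_id = seq_len(n),
                        model = ifelse(is_weibull, "weibull", "kp"),
                        p1 = NA_real_, p2 = NA_real_,
                        noise_sd = config$noise_sd,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      bin <- bins[[sample.int(length(bins), 1)]]
      t_end <- runif(1, max(bin[1], 0.6 * bin[2]), bin[2])
      npts_choices <- seq(config$points_range[1], config$points_range[2])
      npts <- npts_choices[sample.int(length(npts_choices), 1)]
      t0 <- t_end / max(20, npts)
      times <- if (config$time_spacing == "log") {
        exp(seq(log(t0), log(t_end), length.out = npts))
      } else {
        seq(t0, t_end, length.out = npts)
      }
      times <- sort(unique(signif(times, 8)))
      if (is_weibull[i]) {
        tau <- runif(1, 0.15, 0.5) * t_end
        beta <- runif(1, 0.6, 1.4)
        mu <- 100 * weibull_release(times, tau, beta)
        truth[i, c("p1", "p2")] <- c(tau, beta)
      } else {
        nexp <- runif(1, 0.3, 0.9)
        frac_end <- runif(1, 0.6, 0.95)
        k <- frac_end / t_end^nexp
        mu <- 100 * kp_release(times, k, nexp)
        truth[i, c("p1", "p2")] <- c(k, nexp)
      }
      y <- pmax(mu + rnorm(length(times), 0, config$noise_sd), 0)
      y <- pmin(y, 110)   # hard assay ceiling of the schema
      obs[[i]] <- data.frame(sample_id = i, time_h = times, release_pct = y)
    }
    ds <- release_dataset(samples, do.call(rbind, obs),
                          provenance = sprintf("synthetic seed=%d noise_sd=%g",
                                               config$seed, config$noise_sd))
    list(dataset = ds, truth = truth)
  })
}

#' Tiny fixed worked-example dataset
#'
#' A deterministic 3-sample dataset shipped with the package: one sample
#' with Korsmeyer-Peppas truth (curcumin), one with Weibull truth
#' (ibuprofen), and one protein drug (insulin) with two missing carrier
#' fields, exercising the no-structure / imputation path. Stored as plain
#' CSV under `inst/extdata` together with a ground-truth JSON sidecar.
#'
#' @return list with `dataset` and `truth` as in [generate_dataset()].
#' @export
make_worked_fixture <- function() {
  stem <- sub("_samples\\.csv$", "",
              system.file("extdata", "worked_fixture_samples.csv",
                          package = "plgarelease", mustWork = TRUE))
  ds <- read_release_dataset(stem, format = "csv")
  ds$provenance <- "worked fixture (synthetic, fixed)"
  truth <- jsonlite::fromJSON(system.file("extdata",
                                          "worked_fixture_truth.json",
                                          package = "plgarelease",
                                          mustWork = TRUE))
  list(dataset = ds, truth = truth)
}
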