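# Experiment orchestration: corpus x noise spec x operator x selection
# method, with per-cell derived seeds so the whole grid reproduces from one
# master seed. Noise is applied once per (image, noise spec) and shared
# across operators and methods, so method comparisons are paired.

ALL_OPERATORS <- c("sobel", "prewitt", "roberts", "log", "canny")

default_noise_grid <- function() {
  rbind(
    expand.grid(kind = c("gaussian", "salt_pepper", "speckle"),
                intensity = c(0.01, 0.05, 0.1), stringsAsFactors = FALSE),
    expand.grid(kind = "rician", intensity = c(0.05, 0.1, 0.15),
                stringsAsFactors = FALSE)
  )
}

#' Experiment configuration
#'
#' Assembles the full experiment grid: a phantom corpus (counts, size, seed),
#' the noise kinds and intensities (defaults: Gaussian, salt-and-pepper and
#' speckle at 0.01/0.05/0.1; Rician at 0.05/0.1/0.15), the operators, the
#' selection methods (`"standard"`, `"GS"`, `"RS3"`, `"RS6"`, `"RS9"`), the
#' selection metric and matching tolerance, and the candidate-dataset
#' parameters.
#'
#' @param n_per_class phantoms per complexity class (default 10).
#' @param size phantom size `c(h, w)` (default 96 x 96).
#' @param noise data frame with columns `kind`, `intensity`; default the full
#'   12-cell grid above. A `"none"` row runs the clean images.
#' @param operators subset of the five operator names.
#' @param methods subset of `"standard"`, `"GS"`, `"RS3"`, `"RS6"`, `"RS9"`.
#' @param metric selection measure for the searches (`"f"`, `"fom"`, `"pr"`).
#' @param tolerance matching tolerance in pixels for all scoring (default 1).
#' @param alpha FoM constant.
#' @param count_single,count_canny_pairs,low_ratio candidate-dataset
#'   parameters (default: the compact 100-value preset).
#' @param seed master seed; every noise draw and random-search draw derives
#'   its own sub-seed from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_per_class = 10L, size = c(96L, 96L),
                              noise = default_noise_grid(),
                              operators = ALL_OPERATORS,
                              methods = c("standard", "GS", "RS9"),
                              metric = "f", tolerance = 1, alpha = 1 / 9,
                              count_single = 100L, count_canny_pairs = 100L,
                              low_ratio = 0.4, seed = 1L) {
  operators <- match.arg(operators, ALL_OPERATORS, several.ok = TRUE)
  methods <- match.arg(methods, c("standard", "GS", "RS3", "RS6", "RS9"),
                       several.ok = TRUE)
  metric <- match.arg(metric, c("f", "fom", "pr"))
  stopifnot(is.data.frame(noise), nrow(noise) >= 1,
            all(c("kind", "intensity") %in% names(noise)))
  structure(list(n_per_class = as.integer(n_per_class),
                 size = as.integer(size), noise = noise,
                 operators = operators, methods = methods, metric = metric,
                 tolerance = tolerance, alpha = alpha,
                 count_single = as.integer(count_single),
                 count_canny_pairs = as.integer(count_canny_pairs),
                 low_ratio = low_ratio, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Any field of [experiment_config()] may appear in the YAML file; missing
#' fields take the defaults. `noise` is given as a list of
#' `{kind, intensity}` records.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$noise)) {
    y$noise <- do.call(rbind, lapply(y$noise, function(n)
      data.frame(kind = n$kind, intensity = n$intensity)))
  }
  do.call(experiment_config, y)
}

#' Run the full experiment grid
#'
#' Generates (or accepts) the corpus, corrupts each image once per noise spec
#' with a seed derived from the master seed, and runs every configured
#' (operator, method) on the shared noisy image: `standard` is the automatic
#' Otsu baseline, `GS` the exhaustive grid search, and `RSk` the seeded
#' random search with k draws. Each cell is scored on all three measures
#' against the phantom's exact ground truth.
#'
#' @param config an [experiment_config()].
#' @param corpus optional list of `phantom` objects (or lists with `image`,
#'   `gt`, `label` fields); generated from the config when `NULL`.
#' @param verbose print per-image progress to stderr.
#' @return Data frame of experiment records, one row per
#'   (image, noise spec, operator, method) cell: identifiers, the complexity
#'   label, chosen threshold(s), and `f`, `fom`, `pr`, `precision`, `recall`.
#' @export
run_experiment <- function(config, corpus = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(corpus)) {
    corpus <- make_corpus(config$n_per_class, config$size,
                          derive_seed(config$seed, "corpus"))
  }
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  dataset <- generate_threshold_dataset(config$count_single,
                                        config$count_canny_pairs,
                                        config$low_ratio)
  rows <- vector("list", length(corpus) * nrow(config$noise) *
                   length(config$operators) * length(config$methods))
  ri <- 0L
  for (i in seq_along(corpus)) {
    ph <- corpus[[i]]
    image_id <- sprintf("%s_%03d", ph$label, i)
    for (ni in seq_len(nrow(config$noise))) {
      kind <- as.character(config$noise$kind[ni])
      intensity <- config$noise$intensity[ni]
      nseed <- derive_seed(config$seed, image_id, kind, intensity)
      noisy <- apply_noise(ph$image, noise_spec(kind, intensity, nseed))
      if (verbose) {
        message(sprintf("[%s] %s %.2f", image_id, kind, intensity))
      }
      for (op in config$operators) {
        for (method in config$methods) {
          if (method == "standard") {
            det <- standard_detect(noisy, op)
            par <- attr(det, "params")
            thr <- par$threshold
            lo <- par$low
            hi <- par$high
            mseed <- NA_integer_
          } else if (method == "GS") {
            res <- grid_search(noisy, ph$gt, op, dataset,
                               metric = config$metric,
                               tolerance = config$tolerance,
                               alpha = config$alpha)
            det <- res$edge_map
            thr <- res$best$threshold
            lo <- res$best$low
            hi <- res$best$high
            mseed <- NA_integer_
          } else {
            k <- as.integer(sub("RS", "", method))
            mseed <- derive_seed(config$seed, image_id, kind, intensity,
                                 op, method)
            res <- random_search(noisy, ph$gt, op, dataset, k = k,
                                 seed = mseed, metric = config$metric,
                                 tolerance = config$tolerance,
                                 alpha = config$alpha)
            det <- res$edge_map
            thr <- res$best$threshold
            lo <- res$best$low
            hi <- res$best$high
          }
          ev <- evaluate_edges(det, ph$gt, config$tolerance, config$alpha)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            image_id = image_id, label = ph$label,
            noise_kind = kind, intensity = intensity,
            operator = op, method = method,
            threshold = if (is.null(thr)) NA_real_ else thr,
            low = if (is.null(lo)) NA_real_ else lo,
            high = if (is.null(hi)) NA_real_ else hi,
            f = ev$f, fom = ev$fom, pr = ev$pr,
            precision = ev$precision, recall = ev$recall,
            seed = mseed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Summarize experiment records
#'
#' Mean, standard deviation and count of each measure grouped by
#' (complexity label, noise kind, intensity, operator, method).
#'
#' @param records data frame from [run_experiment()].
#' @return Data frame with one row per group and columns
#'   `mean_f`, `sd_f`, `mean_fom`, `mean_pr`, `n`.
#' @export
summarize_experiment <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  grp <- records[c("label", "noise_kind", "intensity", "operator", "method")]
  agg <- aggregate(records[c("f", "fom", "pr")], by = grp, FUN = mean)
  names(agg)[names(agg) == "f"] <- "mean_f"
  names(agg)[names(agg) == "fom"] <- "mean_fom"
  names(agg)[names(agg) == "pr"] <- "mean_pr"
  sds <- aggregate(records["f"], by = grp, FUN = sd)
  ns <- aggregate(records["f"], by = grp, FUN = length)
  agg$sd_f <- sds$f
  agg$n <- ns$f
  agg[order(agg$noise_kind, agg$intensity, agg$label, agg$operator,
            agg$method), ]
}
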