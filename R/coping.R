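# Coping-phenotype classification from resident-intruder defeat
# latencies: per-animal mean latency (900 s cap), 1-D two-means
# clustering, and bootstrap assignment of active/passive labels with an
# exclusion band for unstable classifications.

#' Mean defeat latency for one animal
#'
#' Arithmetic mean of the seven capped daily defeat latencies. A session
#' without a defeat carries the cap value of 900 s.
#'
#' @param sessions Data.frame with columns `day` (1-7, each exactly
#'   once) and `latency_s` (seconds in (0, 900]).
#' @return Mean latency in seconds.
#' @export
mean_latency <- function(sessions) {
  if (!all(c("day", "latency_s") %in% names(sessions)))
    stop("sessions must have columns day and latency_s")
  if (!setequal(sessions$day, 1:7) || nrow(sessions) != 7)
    stop("input error: need days 1-7, each exactly once")
  if (any(sessions$latency_s <= 0 | sessions$latency_s > 900))
    stop("latencies must lie in (0, 900] (900 s cap)")
  mean(sessions$latency_s)
}

#' Per-animal mean latencies from a session table
#'
#' @param sessions Data.frame with columns `animal_id`, `day`,
#'   `latency_s` (7 sessions per animal).
#' @return Named numeric vector of mean latencies, one per animal.
#' @export
mean_latencies <- function(sessions) {
  ids <- unique(sessions$animal_id)
  out <- vapply(ids, function(a)
    mean_latency(sessions[sessions$animal_id == a, ]), numeric(1))
  names(out) <- ids
  out
}

#' Two-cluster partition of mean latencies
#'
#' One-dimensional two-means clustering, solved exactly: in one
#' dimension the optimal two-means partition is a threshold split of
#' the sorted values, so all `n - 1` splits are enumerated and the one
#' minimizing the within-cluster sum of squares is returned (ties go to
#' the leftmost split, making the result deterministic). The cluster
#' with the larger centroid is labeled `active`: active copers resist
#' longer before defeat.
#'
#' @param means Numeric vector of per-animal mean latencies (at least
#'   two distinct values).
#' @return List with `labels` (character vector `"active"`/`"passive"`)
#'   and `centroids` (named `c(passive=, active=)`).
#' @export
#' @examples
#' two_cluster_partition(c(100, 110, 800, 810))
two_cluster_partition <- function(means) {
  if (length(unique(means)) < 2)
    stop("degeneracy error: need at least 2 distinct values")
  o <- order(means)
  xs <- means[o]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wss <- (cs2[k] - cs[k]^2 / k) +
    (cs2[n] - cs2[k] - (cs[n] - cs[k])^2 / (n - k))
  kb <- which.min(wss)
  labels <- character(n)
  labels[o[seq_len(kb)]] <- "passive"
  labels[o[(kb + 1):n]] <- "active"
  list(labels = labels,
       centroids = c(passive = cs[kb] / kb,
                     active = (cs[n] - cs[kb]) / (n - kb)))
}

#' Bootstrap classification of coping phenotype
#'
#' Mean latencies are assumed drawn from a bimodal distribution. For
#' each of `n_boot` bootstrap resamples (animals drawn with
#' replacement), the resample is partitioned by
#' [two_cluster_partition()] and every animal - in-sample or not - is
#' assigned to the nearest centroid. The active probability of an
#' animal is the fraction of resamples in which it lands in the active
#' (longer-latency) cluster: reliably active animals have probability
#' 1.0 and reliably passive animals 0.0. Animals whose probability
#' falls strictly inside the exclusion band (default 0.1-0.9) changed
#' classification in more than 10% of the bootstrap samples and are
#' labeled `excluded`.
#'
#' Resamples whose values are all identical cannot be partitioned and
#' are skipped; if more than 20% of resamples are degenerate the input
#' is not usably bimodal and an error is raised.
#'
#' @param means Numeric vector of per-animal mean latencies (>= 4
#'   animals), optionally named by animal id.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param band Exclusion band edges (default `c(0.1, 0.9)`); labels are
#'   `active` iff probability >= `band[2]`, `passive` iff <= `band[1]`.
#' @return A data.frame with one row per animal: `animal_id`,
#'   `mean_latency_s`, `active_probability`, `label`. The attribute
#'   `"n_degenerate"` counts skipped resamples.
#' @export
bootstrap_classify <- function(means, n_boot = 1000, seed,
                               band = c(0.1, 0.9)) {
  if (length(means) < 4) stop("need at least 4 animals")
  if (missing(seed)) stop("seed is mandatory")
  ids <- names(means) %||% paste0("animal", seq_along(means))
  n <- length(means)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  active_hits <- numeric(n)
  n_used <- 0L; n_degen <- 0L
  for (b in seq_len(n_boot)) {
    samp <- means[sample.int(n, n, replace = TRUE)]
    if (length(unique(samp)) < 2) { n_degen <- n_degen + 1L; next }
    part <- two_cluster_partition(samp)
    mid <- mean(part$centroids)
    active_hits <- active_hits + (means > mid)
    n_used <- n_used + 1L
  }
  if (n_degen > 0.2 * n_boot)
    stop("classification error: more than 20% of bootstrap resamples ",
         "were degenerate; the latency distribution is not bimodal")
  p <- active_hits / n_used
  label <- ifelse(p >= band[2], "active",
                  ifelse(p <= band[1], "passive", "excluded"))
  structure(data.frame(animal_id = ids, mean_latency_s = as.numeric(means),
                       active_probability = p, label = label,
                       row.names = NULL),
            n_degenerate = n_degen)
}

# Save/restore the global RNG state so seeded operations do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Summarize coping assignments
#'
#' @param assignments Output of [bootstrap_classify()].
#' @return List with `counts` (table over active/passive/excluded) and
#'   `excluded` (the rows of excluded animals, with probabilities).
#' @export
exclusion_report <- function(assignments) {
  counts <- table(factor(assignments$label,
                         c("active", "passive", "excluded")))
  list(counts = counts,
       excluded = assignments[assignments$label == "excluded", ])
}

#' Read a defeat-latency table
#'
#' @param path CSV with columns `animal_id`, `day`, `latency_s`.
#' @return The validated data.frame.
#' @export
read_latency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day", "latency_s")
  if (!all(need %in% names(df)))
    stop("latency CSV must have columns ", paste(need, collapse = ", "))
  df
}
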