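# Index-level cohort simulation. Each diagnostic group is described by a
# marginal Gaussian per sport index (the published tables report only
# mean +/- SD, so no correlation structure is imposed); draws that land
# non-positive are resampled, since every index is a positive quantity.

#' Specify a simulated four-group cohort
#'
#' Group sizes and per-index means/SDs for the male/female athlete and HCM
#' groups. Defaults are the published group statistics
#' ([reference_group_stats()]): sizes 101/108/49/86 and the printed
#' mean +/- SD of each sport index.
#'
#' @param stats data frame with columns `group`, `sex`, `diagnosis`, `n`,
#'   `index`, `mean`, `sd` (one row per group-index pair).
#' @param seed integer seed for sampling.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(stats = reference_group_stats(), seed = 1L) {
  need <- c("group", "sex", "diagnosis", "n", "index", "mean", "sd")
  if (!all(need %in% names(stats)))
    stop_cmr("'stats' must have columns %s", paste(need, collapse = ", "))
  if (any(stats$n < 0)) stop_cmr("group sizes must be >= 0")
  if (any(stats$sd <= 0)) stop_cmr("all SDs must be > 0")
  if (any(!stats$diagnosis %in% c("athlete", "HCM")))
    stop_cmr("diagnosis must be 'athlete' or 'HCM'")
  ntab <- unique(stats[, c("group", "n")])
  if (anyDuplicated(ntab$group))
    stop_cmr("inconsistent 'n' within a group")
  structure(list(stats = stats, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a simulated subject-by-index table
#'
#' Draws each subject's sport indices as independent Gaussians with the
#' group's mean and SD, resampling any non-positive draw. Reproducible under
#' the spec's seed.
#'
#' @param cohort a [cohort_spec()].
#' @return Data frame: `subject_id`, `group`, `sex`, `diagnosis`, plus one
#'   column per index.
#' @examples
#' head(sample_cohort(cohort_spec(seed = 7)))
#' @export
sample_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort_spec")) stop_cmr("need a 'cohort_spec'")
  st <- cohort$stats
  groups <- unique(st$group)
  with_seed(cohort$seed, {
    rows <- lapply(groups, function(g) {
      sg <- st[st$group == g, , drop = FALSE]
      n <- sg$n[1L]
      if (n == 0L) return(NULL)
      out <- data.frame(subject_id = paste0(g, "_", seq_len(n)),
                        group = g, sex = sg$sex[1L],
                        diagnosis = sg$diagnosis[1L],
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(sg))) {
        x <- stats::rnorm(n, sg$mean[i], sg$sd[i])
        bad <- x <= 0
        while (any(bad)) {
          x[bad] <- stats::rnorm(sum(bad), sg$mean[i], sg$sd[i])
          bad <- x <= 0
        }
        out[[sg$index[i]]] <- x
      }
      out
    })
    do.call(rbind, rows)
  })
}
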