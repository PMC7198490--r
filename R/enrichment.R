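#' Gene-set enrichment of association slopes
#'
#' Weighted running-sum enrichment test of the per-feature slopes against
#' annotated gene sets. Features are ranked by decreasing slope (ties
#' broken by a stable sort on feature ID); walking down the ranking, hits
#' add `|slope| / sum(|slope| over hits)` and misses subtract
#' `1 / (N - n_hits)`, and the enrichment score (ES) is the running sum at
#' its maximum absolute deviation. Positive ES marks concentration among
#' up-regulated features, negative ES among down-regulated ones -- the
#' separate up/down readout. The null distribution comes from permuting
#' the feature labels of the slope vector; the two-sided p-value uses the
#' `(b + 1)/(N + 1)` Monte-Carlo estimator. Null scores are shared across
#' sets of equal size (the label-permutation null depends on the set only
#' through its size).
#'
#' Sets with fewer than 2 members mapped to the slope vector are skipped
#' with a warning.
#'
#' @param slopes A tibble with columns `feature` and `estimate` (as
#'   returned by [oc_associations()]), or a named numeric vector.
#' @param sets Named list of feature-ID vectors (see [read_gmt()]).
#' @param n_perm Number of label permutations for the null.
#' @param seed Integer seed.
#' @return A tibble with one row per tested set: `set`, `size`, `es`,
#'   `direction`, `p_value`, `n_used`.
#' @export
#' @examples
#' slopes <- tibble::tibble(feature = paste0("g", 1:50),
#'                          estimate = c(rep(1, 5), rnorm(45, 0, 0.2)))
#' sets <- list(top = paste0("g", 1:5), random = paste0("g", 21:30))
#' gene_set_enrichment(slopes, sets, n_perm = 200, seed = 1)
gene_set_enrichment <- function(slopes, sets, n_perm = 1000, seed = 1L) {
  if (is.numeric(slopes)) {
    slopes <- tibble::tibble(feature = names(slopes), estimate = unname(slopes))
  }
  if (!all(c("feature", "estimate") %in% names(slopes))) {
    abort("gene_set_enrichment: `slopes` needs `feature` and `estimate` columns.",
          class = "formateswitch_domain_error")
  }
  if (any(!is.finite(slopes$estimate))) {
    abort("gene_set_enrichment: slopes must be finite.",
          class = "formateswitch_domain_error")
  }
  if (!length(sets)) {
    abort("gene_set_enrichment: need at least one gene set.",
          class = "formateswitch_domain_error")
  }

  ord <- order(-slopes$estimate, slopes$feature, method = "radix")
  stat <- slopes$estimate[ord]
  feats <- slopes$feature[ord]
  N <- length(stat)

  sizes <- vapply(sets, function(s) length(intersect(s, feats)), integer(1))
  keep <- sizes >= 2L
  if (any(!keep)) {
    warn(paste0("gene_set_enrichment: skipping set(s) with < 2 mapped features: ",
                paste(names(sets)[!keep], collapse = ", ")))
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (!length(sets)) {
    return(tibble::tibble(set = character(), size = integer(), es = numeric(),
                          direction = character(), p_value = numeric(),
                          n_used = integer()))
  }

  # one null ES sample per set size, shared across equal-sized sets
  null_by_size <- with_seed_local(seed, {
    lapply(setNames(unique(sizes), unique(sizes)), function(k) {
      vapply(seq_len(n_perm), function(i) {
        .es_score(stat, sample.int(N, k))
      }, numeric(1))
    })
  })

  purrr::imap(sets, function(members, nm) {
    hits <- which(feats %in% members)
    es <- .es_score(stat, hits)
    null_es <- null_by_size[[as.character(length(hits))]]
    p <- .perm_pvalue(es, null_es, exhaustive = FALSE,
                      alternative = "two_sided")
    tibble::tibble(set = nm, size = length(hits), es = es,
                   direction = if (es >= 0) "up" else "down",
                   p_value = p, n_used = n_perm)
  }) |>
    dplyr::bind_rows()
}

# weighted Kolmogorov-Smirnov-like running sum; `stat` is sorted decreasing
.es_score <- function(stat, hit_positions) {
  N <- length(stat)
  k <- length(hit_positions)
  w <- abs(stat[hit_positions])
  sw <- sum(w)
  delta <- rep(-1 / (N - k), N)
  if (sw > 0) {
    delta[hit_positions] <- w / sw
  } else {
    delta[hit_positions] <- 1 / k # all-zero stats: unweighted walk
  }
  run <- cumsum(delta)
  run[which.max(abs(run))]
}
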