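#' One-carbon availability index lookup
#'
#' Maps condition labels to their one-carbon availability index through a
#' condition design table (see [gen_condition_design()] for the standard
#' six-condition design: index 0 for the MFT-SHMT1 double knockout, 1 for
#' the MFT and SHMT2 single knockouts, 2 for the formate-supplemented
#' knockouts and the parental WT).
#'
#' @param condition Character vector of condition labels.
#' @param design A design tibble with columns `condition` and `oc_index`.
#' @return Integer vector of indices.
#' @export
#' @examples
#' assign_oc_index(c("WT", "MFT-SHMT1"), gen_condition_design())
assign_oc_index <- function(condition, design) {
  idx <- match(condition, design$condition)
  if (anyNA(idx)) {
    abort(paste0("assign_oc_index: unknown condition label(s): ",
                 paste(unique(condition[is.na(idx)]), collapse = ", ")),
          class = "formateswitch_domain_error")
  }
  as.integer(design$oc_index[idx])
}

#' Association statistics against the one-carbon availability index
#'
#' `index_slope()` is the ordinary least-squares slope of a response
#' (log2 intensity) on the ordinal index; `spearman_index()` is the
#' Spearman rank correlation (average ranks for ties, Pearson correlation
#' of the ranks).
#'
#' @param values Numeric response vector.
#' @param indices Numeric index vector (same length).
#' @return A single number: the slope (log2 units per index step) or the
#'   rank correlation `S` in `[-1, 1]`.
#' @export
#' @examples
#' index_slope(c(0, 1, 2), c(0, 1, 2)) # 1
#' spearman_index(c(5, 7, 9, 20), c(0, 1, 1, 2)) # 1 up to ties
index_slope <- function(values, indices) {
  keep <- is.finite(values) & is.finite(indices)
  x <- indices[keep]; y <- values[keep]
  if (length(unique(x)) < 2L) {
    abort("index_slope: need >= 2 distinct index values.",
          class = "formateswitch_domain_error")
  }
  .ols_slope(x, y)
}

#' @rdname index_slope
#' @export
spearman_index <- function(values, indices) {
  keep <- is.finite(values) & is.finite(indices)
  if (sum(keep) < 3L) {
    abort("spearman_index: need >= 3 observations.",
          class = "formateswitch_domain_error")
  }
  cor(values[keep], indices[keep], method = "spearman")
}

# all permutations of 1..n as an (n! x n) integer matrix, n <= 9
.all_perms <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

# permutation index matrix: exhaustive when feasible (or forced), else
# Monte-Carlo draws
.perm_matrix <- function(n_units, n_perm, seed, exhaustive = "auto") {
  exhaustive <- switch(exhaustive,
    auto = n_units <= 9L && factorial(n_units) <= n_perm,
    never = FALSE,
    always = {
      if (n_units > 9L) {
        abort("exhaustive enumeration limited to 9 units.",
              class = "formateswitch_domain_error")
      }
      TRUE
    }
  )
  if (exhaustive) {
    list(perms = .all_perms(n_units), exhaustive = TRUE)
  } else {
    perms <- with_seed_local(seed, {
      t(replicate(n_perm, sample.int(n_units)))
    })
    list(perms = perms, exhaustive = FALSE)
  }
}

.perm_pvalue <- function(obs, null_stats, exhaustive,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tol <- 1e-12 * max(abs(c(obs, null_stats)), 1e-300) # ties count as hits
  b <- switch(alternative,
    two_sided = sum(abs(null_stats) >= abs(obs) - tol),
    greater = sum(null_stats >= obs - tol),
    less = sum(null_stats <= obs + tol)
  )
  if (exhaustive) b / length(null_stats) else (b + 1) / (length(null_stats) + 1)
}

#' Permutation p-value for an association statistic
#'
#' Permutes the values across the condition labels and compares the
#' permuted statistics against the observed one. When the number of
#' distinct assignments (`n!` for `n` conditions) is at most `n_perm`, the
#' permutation distribution is enumerated exhaustively and the p-value is
#' the exact fraction `b/N` with the identity included; otherwise `n_perm`
#' Monte-Carlo permutations are drawn and the estimator is
#' `p = (b + 1)/(N + 1)`, whose smallest attainable value is
#' `1/(n_perm + 1)` (never zero).
#'
#' @param values Numeric vector of condition-level values.
#' @param indices Condition indices (the covariate of `stat_fn`).
#' @param stat_fn Statistic `function(values, indices)`; defaults to
#'   [index_slope()].
#' @param n_perm Number of Monte-Carlo permutations (and the budget above
#'   which exhaustive enumeration is abandoned).
#' @param seed Integer seed (Monte-Carlo mode only).
#' @param alternative `"two_sided"` (on the absolute statistic),
#'   `"greater"` or `"less"`.
#' @param exhaustive `"auto"` (enumerate whenever `n! <= n_perm`),
#'   `"never"` (force Monte-Carlo) or `"always"`.
#' @return A one-row tibble: `observed`, `p_value`, `n_used`, `exhaustive`.
#' @export
#' @examples
#' # only the identity ordering of (1,2,3) attains slope >= 1: p = 1/6
#' permutation_p(c(1, 2, 3), c(0, 1, 2), alternative = "greater")
permutation_p <- function(values, indices, stat_fn = index_slope,
                          n_perm = 10000, seed = 1L,
                          alternative = c("two_sided", "greater", "less"),
                          exhaustive = c("auto", "never", "always")) {
  alternative <- match.arg(alternative)
  exhaustive <- match.arg(exhaustive)
  if (n_perm < 1) {
    abort("permutation_p: `n_perm` must be >= 1.",
          class = "formateswitch_domain_error")
  }
  n <- length(values)
  if (n != length(indices) || length(unique(indices)) < 2L) {
    abort("permutation_p: need matching vectors with >= 2 groups.",
          class = "formateswitch_domain_error")
  }
  obs <- stat_fn(values, indices)
  pm <- .perm_matrix(n, n_perm, seed, exhaustive)
  null_stats <- vapply(seq_len(nrow(pm$perms)), function(i) {
    stat_fn(values[pm$perms[i, ]], indices)
  }, numeric(1))
  p <- .perm_pvalue(obs, null_stats, pm$exhaustive, alternative)
  tibble::tibble(observed = obs, p_value = p,
                 n_used = nrow(pm$perms), exhaustive = pm$exhaustive)
}

# split "<condition>_R<k>" column labels of a wide omics table
.split_omics_columns <- function(cols) {
  cond <- sub("_R\\d+$", "", cols)
  rep <- sub("^.*_R(\\d+)$", "\\1", cols)
  if (any(rep == cols)) {
    abort("omics table columns must be labelled '<condition>_R<replicate>'.",
          class = "formateswitch_domain_error")
  }
  tibble::tibble(column = cols, condition = cond, replicate = as.integer(rep))
}

# log2 with zero/negative masking (feature dropped for that measurement)
.log2_masked <- function(m) {
  out <- suppressWarnings(log2(m))
  out[!is.finite(out)] <- NA_real_
  out
}

# condition-level summary matrix (replicates averaged) on log2 scale
.condition_summaries <- function(table, design, scale) {
  feats <- table$feature
  if (anyDuplicated(feats)) {
    abort("omics table has duplicated feature IDs.",
          class = "formateswitch_domain_error")
  }
  m <- as.matrix(table[setdiff(names(table), "feature")])
  info <- .split_omics_columns(colnames(m))
  unknown <- setdiff(unique(info$condition), design$condition)
  if (length(unknown)) {
    abort(paste0("conditions not present in the design: ",
                 paste(unknown, collapse = ", ")),
          class = "formateswitch_domain_error")
  }
  if (scale == "raw") {
    if (any(m < 0, na.rm = TRUE)) {
      abort("raw-scale omics table contains negative values.",
            class = "formateswitch_domain_error")
    }
    m <- .log2_masked(m)
  }
  conds <- intersect(design$condition, unique(info$condition))
  summ <- vapply(conds, function(cc) {
    cols <- info$column[info$condition == cc]
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  summ[is.nan(summ)] <- NA_real_
  rownames(summ) <- feats
  list(summary = summ, log2 = m, info = info, conditions = conds)
}

#' Per-feature association of an omics table with the one-carbon index
#'
#' Computes, for every feature of an intensity/peak-area table, an
#' association statistic against the one-carbon availability index
#' ([index_slope()] of the log2 values by default, or [spearman_index()])
#' together with a permutation p-value. Raw tables are log2-transformed
#' first with zeros masked; replicates are averaged within condition before
#' permuting, so the permutation unit is the condition (cell
#' line/treatment), matching a design where conditions, not replicates,
#' are exchangeable under the null. `permute = "replicate"` instead keeps
#' replicate-level values and moves replicate blocks with their condition
#' label.
#'
#' Exhaustive enumeration replaces Monte-Carlo sampling whenever the
#' number of condition orderings is at most `n_perm` (720 for the standard
#' six-condition design), giving exact p-values.
#'
#' @param table Wide omics tibble: `feature` column plus
#'   `<condition>_R<k>` intensity columns.
#' @param design Condition design tibble (see [gen_condition_design()]).
#' @param stat `"slope"` or `"spearman"`.
#' @param n_perm Permutation budget.
#' @param seed Integer seed.
#' @param alternative Sidedness of the p-value.
#' @param scale `"raw"` or `"log2"`; defaults to the table's
#'   `value_scale` attribute, else `"raw"`.
#' @param permute Permutation unit, `"condition"` (default) or
#'   `"replicate"`.
#' @param adjust Add a Benjamini--Hochberg adjusted column `p_adjusted`
#'   (off by default; raw permutation p-values are always reported).
#' @return A tibble with one row per feature: `feature`, `stat`,
#'   `estimate`, `p_value`, (`p_adjusted`,) `n_used`, `exhaustive`.
#' @export
#' @examples
#' design <- gen_condition_design()
#' sim <- gen_proteomics(n_features = 20, frac_responsive = 0.5,
#'                       design = design, seed = 1)
#' oc_associations(sim$table, design, n_perm = 720, seed = 1)
oc_associations <- function(table, design, stat = c("slope", "spearman"),
                            n_perm = 10000, seed = 1L,
                            alternative = c("two_sided", "greater", "less"),
                            scale = NULL, permute = c("condition", "replicate"),
                            adjust = FALSE) {
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  permute <- match.arg(permute)
  scale <- scale %||% attr(table, "value_scale") %||% "raw"
  scale <- match.arg(scale, c("raw", "log2"))

  cs <- .condition_summaries(table, design, scale)
  cond_idx <- assign_oc_index(cs$conditions, design)

  if (permute == "condition") {
    Y <- cs$summary                      # features x conditions
    x <- cond_idx
    block <- seq_along(cs$conditions)    # one unit per condition
  } else {
    info <- cs$info
    ord <- order(match(info$condition, cs$conditions), info$replicate)
    Y <- cs$log2[, info$column[ord], drop = FALSE]
    x <- cond_idx[match(info$condition[ord], cs$conditions)]
    block <- match(info$condition[ord], cs$conditions)
  }

  pm <- .perm_matrix(length(cs$conditions), n_perm, seed)
  n_used <- nrow(pm$perms)

  # a condition permutation reorders the per-condition blocks of columns
  col_perms <- matrix(0L, n_used, ncol(Y))
  by_block <- split(seq_len(ncol(Y)), block)
  for (i in seq_len(n_used)) {
    col_perms[i, ] <- unlist(by_block[pm$perms[i, ]], use.names = FALSE)
  }

  stat_fn <- if (stat == "slope") index_slope else spearman_index
  res <- vapply(seq_len(nrow(Y)), function(f) {
    y <- Y[f, ]
    obs <- stat_fn(y, x)
    null_stats <- vapply(seq_len(n_used), function(i) {
      stat_fn(y[col_perms[i, ]], x)
    }, numeric(1))
    c(obs, .perm_pvalue(obs, null_stats, pm$exhaustive, alternative))
  }, numeric(2))

  out <- tibble::tibble(
    feature = table$feature,
    stat = if (stat == "slope") "slope" else "spearman_S",
    estimate = res[1L, ],
    p_value = res[2L, ],
    n_used = n_used,
    exhaustive = pm$exhaustive
  )
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Welch two-sample t test
#'
#' Two-sided t test with unequal variances (Satterthwaite degrees of
#' freedom), the package's standard two-group comparison.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 7))
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("welch_t: need at least 2 values per group.",
          class = "formateswitch_domain_error")
  }
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2,
                          p_value = 1, mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Total protein mass associated with annotated pathways
#'
#' Sums the raw-scale intensities of a gene set's member features within
#' each condition (replicates averaged first), the per-pathway protein
#' mass readout. Requires a raw-scale table; member features missing from
#' the table are ignored.
#'
#' @param table Wide raw-scale omics tibble (`feature` +
#'   `<condition>_R<k>` columns).
#' @param sets Named list of feature-ID vectors (see [read_gmt()]), or a
#'   single character vector.
#' @return A tibble with columns `set`, `condition`, `mass`.
#' @export
pathway_mass <- function(table, sets) {
  scale <- attr(table, "value_scale") %||% "raw"
  if (!identical(scale, "raw")) {
    abort("pathway_mass: requires a raw-scale table.",
          class = "formateswitch_domain_error")
  }
  if (!is.list(sets)) sets <- list(set = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  m <- as.matrix(table[setdiff(names(table), "feature")])
  info <- .split_omics_columns(colnames(m))
  conds <- unique(info$condition)
  avg <- vapply(conds, function(cc) {
    rowMeans(m[, info$column[info$condition == cc], drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  rownames(avg) <- table$feature
  purrr::imap(sets, function(members, nm) {
    rows <- intersect(members, table$feature)
    mass <- if (length(rows)) colSums(avg[rows, , drop = FALSE]) else
      setNames(rep(0, length(conds)), conds)
    tibble::tibble(set = nm, condition = conds, mass = unname(mass))
  }) |>
    dplyr::bind_rows()
}
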