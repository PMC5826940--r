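# Montage-comparison statistics: one-way fixed-effects ANOVA across the
# montages with head models as replicates, Bonferroni-corrected pooled-
# variance pairwise t tests, and absolute Cohen's d effect sizes.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  short <- vapply(groups, length, integer(1)) < 2
  if (any(short))
    stop("every group needs at least 2 values (offending group(s): ",
         paste(which(short), collapse = ", "), ")")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way fixed-effects ANOVA
#'
#' Standard F test of equal group means with degrees of freedom
#' `(k - 1, N - k)`, computed through [stats::aov()].
#'
#' @param groups Named list of numeric vectors (>= 2 values each).
#' @return List with `F`, `p`, `df` (length 2).
#' @export
#' @examples
#' anova_oneway(list(a = 1:3, b = 2:4, c = 3:5))$F  # 3
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  tab <- summary(aov(value ~ group, data = dat))[[1]]
  Fv <- tab[["F value"]][1]
  if (is.na(Fv)) Fv <- 0  # zero within- and between-group variance
  list(F = Fv, p = if (is.na(tab[["Pr(>F)"]][1])) 1 else tab[["Pr(>F)"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]))
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Two-sided pooled-variance two-sample t tests for every pair of groups,
#' with raw p-values multiplied by the number of pairs and capped at 1.
#'
#' @param groups Named list of numeric vectors (>= 2 values each).
#' @return Data frame with `pair`, `a`, `b`, `t`, `p_raw`, `p_adj`,
#'   `mean_diff`.
#' @export
bonferroni_pairwise <- function(groups) {
  groups <- check_groups(groups)
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    a <- groups[[i]]; b <- groups[[j]]
    if (sd(c(a - mean(a), b - mean(b))) == 0) {
      # zero pooled variance: equal means are indistinguishable (p = 1);
      # distinct constant groups separate with certainty
      if (mean(a) == mean(b)) tt <- list(statistic = c(t = 0), p.value = 1)
      else tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                      p.value = .Machine$double.xmin)
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
    }
    data.frame(pair = paste(nm[i], "vs", nm[j]), a = nm[i], b = nm[j],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * n_pairs),
               mean_diff = mean(a) - mean(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled sample standard
#' deviation; tables report the absolute value.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return Signed d (antisymmetric in its arguments).
#' @export
#' @examples
#' abs(cohens_d(1:3, 3:5))  # 2
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("Cohen's d is undefined for zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Montage-comparison report
#'
#' Shapes a tidy metrics table into the two canonical report tables: one row
#' per ROI for peak field (at a single reference amplitude) and one row per
#' network side x amplitude for modulated volume, each carrying the one-way
#' ANOVA F and p, Bonferroni-adjusted pairwise p-values with `*`/`**`/`***`
#' significance at 0.05/0.01/0.001, and absolute Cohen's d per montage pair.
#'
#' @param metrics Data frame with columns `head`, `montage`, `amplitude`,
#'   `measure` (`"peak_field"` or `"modulated_volume"`), `target` (ROI name
#'   or side), `value`, for all montages in `montages`.
#' @param montages Character vector of montage names to compare (>= 2).
#' @param peak_amplitude Amplitude (mA) at which the peak-field table is
#'   reported.
#' @return List of class `stats_report` with data frames `peak_field` and
#'   `modulated_volume`.
#' @export
build_report <- function(metrics, montages = c("LUL", "BL", "TWO_BY_ONE"),
                         peak_amplitude = 2) {
  needed <- c("head", "montage", "amplitude", "measure", "target", "value")
  if (!all(needed %in% names(metrics)))
    stop("metrics must have columns ", paste(needed, collapse = ", "))
  missing <- setdiff(montages, unique(metrics$montage))
  if (length(missing) > 0)
    stop("metrics are missing montage(s): ", paste(missing, collapse = ", "))

  one_outcome <- function(sub) {
    groups <- lapply(montages, function(m) sub$value[sub$montage == m])
    names(groups) <- montages
    av <- anova_oneway(groups)
    pw <- bonferroni_pairwise(groups)
    # saturated outcomes (identical values in both groups, e.g. 0% or 100%
    # modulated volume in every head) have zero pooled variance: report
    # d = 0 for equal means, Inf for separated constants
    d <- mapply(function(a, b) {
      ga <- groups[[a]]; gb <- groups[[b]]
      tryCatch(abs(cohens_d(ga, gb)),
               error = function(e) if (mean(ga) == mean(gb)) 0 else Inf)
    }, pw$a, pw$b)
    row <- data.frame(F = av$F, p = av$p,
                      df1 = av$df[1], df2 = av$df[2],
                      stringsAsFactors = FALSE)
    for (q in seq_len(nrow(pw))) {
      key <- gsub(" ", "_", pw$pair[q])
      row[[paste0("p_adj_", key)]] <- pw$p_adj[q]
      row[[paste0("sig_", key)]] <- significance_stars(pw$p_adj[q])
      row[[paste0("d_", key)]] <- d[q]
    }
    row
  }

  pk <- metrics[metrics$measure == "peak_field" &
                  metrics$amplitude == peak_amplitude, ]
  peak_rows <- lapply(split(pk, pk$target), one_outcome)
  peak_tab <- cbind(data.frame(roi = names(peak_rows)),
                    do.call(rbind, peak_rows))
  rownames(peak_tab) <- NULL

  mv <- metrics[metrics$measure == "modulated_volume", ]
  mv$key <- paste(mv$target, mv$amplitude, sep = "@")
  mv_rows <- lapply(split(mv, mv$key), one_outcome)
  key_parts <- strsplit(names(mv_rows), "@", fixed = TRUE)
  mv_tab <- cbind(
    data.frame(side = vapply(key_parts, `[`, "", 1),
               amplitude = as.numeric(vapply(key_parts, `[`, "", 2))),
    do.call(rbind, mv_rows))
  mv_tab <- mv_tab[order(mv_tab$side, mv_tab$amplitude), ]
  rownames(mv_tab) <- NULL

  structure(list(peak_field = peak_tab, modulated_volume = mv_tab,
                 montages = montages, peak_amplitude = peak_amplitude),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> montages:", paste(x$montages, collapse = ", "), "\n")
  cat(sprintf("Peak field (at %g mA), one row per ROI:\n", x$peak_amplitude))
  print(x$peak_field, digits = 3)
  cat("Modulated volume, one row per side x amplitude:\n")
  print(x$modulated_volume, digits = 3)
  invisible(x)
}
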