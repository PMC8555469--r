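#' Median split of subjects by online BCI accuracy
#'
#' Subjects strictly above the median accuracy form the High group,
#' strictly below the Low group; subjects exactly at the median are
#' excluded. For an odd cohort with distinct accuracies this removes
#' exactly one subject and leaves two equal-sized groups (55 subjects ->
#' 27 High + 27 Low + 1 excluded).
#'
#' @param accuracies Data frame with columns `subject_id` and
#'   `accuracy_percent` (as from [draw_accuracies()]), or a named numeric
#'   vector of accuracies.
#' @return Object of class `group_assignment`: list with `assignment`
#'   (tibble subject_id, accuracy_percent, group), `excluded` (character
#'   vector of excluded subject ids) and `median` (the split value).
#' @export
median_split <- function(accuracies) {
  if (is.numeric(accuracies)) {
    accuracies <- tibble::tibble(
      subject_id = if (is.null(names(accuracies)))
        sprintf("S%02d", seq_along(accuracies)) else names(accuracies),
      accuracy_percent = unname(accuracies))
  }
  acc <- accuracies$accuracy_percent
  if (length(acc) < 3) stop("need at least 3 subjects for a median split")
  if (length(unique(acc)) == 1L) {
    stop("all accuracies identical: no median split possible")
  }
  med <- stats::median(acc)
  grp <- ifelse(acc > med, "High", ifelse(acc < med, "Low", NA_character_))
  structure(
    list(assignment = tibble::tibble(
           subject_id = accuracies$subject_id[!is.na(grp)],
           accuracy_percent = acc[!is.na(grp)],
           group = grp[!is.na(grp)]),
         excluded = accuracies$subject_id[is.na(grp)],
         median = med),
    class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(x$assignment$group)
  cat(sprintf("<group_assignment> median %.2f%%: %d High, %d Low, %d excluded\n",
              x$median, tab["High"], tab["Low"], length(x$excluded)))
  invisible(x)
}

# Type-II sums of squares for a 2-factor design with interaction, computed
# as differences of fitted sums of squares between nested models; operates
# column-wise on a response matrix so all permutations are handled in one
# pass of matrix algebra.
anova_2x2_f <- function(Y, A, B) {
  n <- nrow(Y)
  XB <- stats::model.matrix(~B)
  XA <- stats::model.matrix(~A)
  XAB <- stats::model.matrix(~A + B)
  Xfull <- stats::model.matrix(~A * B)
  qb <- qr(XB); qa <- qr(XA); qab <- qr(XAB); qf <- qr(Xfull)
  ssr <- function(q) colSums(qr.fitted(q, Y)^2)
  ssr_b <- ssr(qb); ssr_a <- ssr(qa); ssr_ab <- ssr(qab); ssr_f <- ssr(qf)
  sse <- colSums(Y^2) - ssr_f
  df_a <- qab$rank - qb$rank
  df_b <- qab$rank - qa$rank
  df_i <- qf$rank - qab$rank
  df_e <- n - qf$rank
  if (df_e < 1) stop("no residual degrees of freedom")
  list(
    F = rbind(group = ((ssr_ab - ssr_b) / df_a) / (sse / df_e),
              hand = ((ssr_ab - ssr_a) / df_b) / (sse / df_e),
              interaction = ((ssr_f - ssr_ab) / df_i) / (sse / df_e)),
    df1 = c(group = df_a, hand = df_b, interaction = df_i),
    df2 = df_e)
}

#' Permutation two-way factorial ANOVA
#'
#' Classical two-way ANOVA F statistics (Type-II sums of squares) for the
#' group and hand main effects and their interaction, with p-values from a
#' permutation null: p = (b + 1) / (n_perm + 1) where b counts permuted F
#' statistics at least as large as the observed one.
#'
#' Permutation schemes:
#' \describe{
#'   \item{manly}{(default) the response vector is permuted freely across
#'     all observations; each permutation yields all three F statistics.
#'     Valid when the global null renders the observations exchangeable.}
#'   \item{subject}{restricted permutations respecting the repeated
#'     measure: the group effect permutes whole subject blocks (both hand
#'     rows of a subject move together), the hand effect flips hand labels
#'     within subjects, and the interaction uses free permutation.}
#' }
#'
#' @param data Data frame with columns `subject`, `group`, `hand`, `value`
#'   (one row per subject x hand).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param scheme "manly" or "subject".
#' @return Tibble: effect, F_obs, df1, df2, p_perm, n_perm.
#' @export
perm_anova_2x2 <- function(data, n_perm = 999, seed = NULL,
                           scheme = c("manly", "subject")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  need <- c("subject", "group", "hand", "value")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "))
  }
  A <- factor(data$group)
  B <- factor(data$hand)
  y <- data$value
  n <- length(y)
  if (any(table(A, B) == 0)) stop("empty cell in the 2x2 design")

  if (scheme == "manly") {
    Y <- matrix(0, n, n_perm + 1L)
    Y[, 1] <- y
    for (p in seq_len(n_perm)) Y[, p + 1L] <- y[sample.int(n)]
    res <- anova_2x2_f(Y, A, B)
    Fm <- res$F
    p_perm <- vapply(rownames(Fm), function(e) {
      (sum(Fm[e, -1] >= Fm[e, 1]) + 1) / (n_perm + 1)
    }, numeric(1))
    F_obs <- Fm[, 1]
  } else {
    subj <- factor(data$subject)
    subj_ids <- levels(subj)
    ns <- length(subj_ids)
    rows_of <- split(seq_len(n), subj)
    # group effect: permute subject blocks
    Yg <- matrix(0, n, n_perm + 1L); Yg[, 1] <- y
    # hand effect: flip hands within subject
    Yh <- matrix(0, n, n_perm + 1L); Yh[, 1] <- y
    # interaction: free permutation
    Yi <- matrix(0, n, n_perm + 1L); Yi[, 1] <- y
    for (p in seq_len(n_perm)) {
      perm_s <- sample.int(ns)
      new_y <- y
      for (s in seq_len(ns)) {
        src <- rows_of[[perm_s[s]]]
        dst <- rows_of[[s]]
        # align by hand label within the block
        src <- src[match(data$hand[dst], data$hand[src])]
        new_y[dst] <- y[src]
      }
      Yg[, p + 1L] <- new_y
      flip <- stats::runif(ns) < 0.5
      hy <- y
      for (s in which(flip)) {
        r <- rows_of[[s]]
        hy[r] <- y[rev(r)]
      }
      Yh[, p + 1L] <- hy
      Yi[, p + 1L] <- y[sample.int(n)]
    }
    rg <- anova_2x2_f(Yg, A, B)
    rh <- anova_2x2_f(Yh, A, B)
    ri <- anova_2x2_f(Yi, A, B)
    res <- rg  # df bookkeeping identical across schemes
    F_obs <- c(group = unname(rg$F["group", 1]),
               hand = unname(rh$F["hand", 1]),
               interaction = unname(ri$F["interaction", 1]))
    p_perm <- c(
      group = (sum(rg$F["group", -1] >= rg$F["group", 1]) + 1) / (n_perm + 1),
      hand = (sum(rh$F["hand", -1] >= rh$F["hand", 1]) + 1) / (n_perm + 1),
      interaction = (sum(ri$F["interaction", -1] >=
                           ri$F["interaction", 1]) + 1) / (n_perm + 1))
  }
  tibble::tibble(
    effect = c("group", "hand", "interaction"),
    F_obs = unname(F_obs[c("group", "hand", "interaction")]),
    df1 = unname(res$df1[c("group", "hand", "interaction")]),
    df2 = res$df2,
    p_perm = unname(p_perm[c("group", "hand", "interaction")]),
    n_perm = n_perm)
}

# Welch t statistic; 0 when both samples are degenerate with equal means,
# +/- Inf when degenerate with different means
welch_t <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / length(a) + vb / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(se2)
}

#' Two-sample permutation t-test
#'
#' Welch t statistic on the observed samples; the null distribution is
#' built by randomly relabeling the pooled observations into two samples
#' of the original sizes. Two-sided p = (b + 1)/(n_perm + 1) with b the
#' count of permuted |t| >= observed |t|.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return Tibble: t_obs, p_perm, n_perm.
#' @export
perm_ttest <- function(a, b, n_perm = 999, seed = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need >= 2 values")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t_obs <- welch_t(a, b)
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  count <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    tp <- welch_t(pooled[idx], pooled[-idx])
    if (!is.nan(tp) && abs(tp) >= abs(t_obs)) count <- count + 1L
  }
  p_val <- if (t_obs == 0) 1 else (count + 1) / (n_perm + 1)
  tibble::tibble(t_obs = t_obs, p_perm = p_val, n_perm = n_perm)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (default 6: three activity types, rest /
#'   motor imagery / delta, times two frequency bands).
#' @return alpha / m (0.05 / 6 = 0.00833..., conventionally displayed as
#'   0.008).
#' @export
bonferroni <- function(alpha = 0.05, m = 6) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Group comparison of scale-averaged PLV
#'
#' Joins a scale-averaged PLV table with a group assignment and runs the
#' permutation factorial ANOVA (group x imagery hand) for every
#' (scale, window, band) cell.
#'
#' @param scale_table Output of [scale_average()] with conditions left and
#'   right (one value per subject x hand after averaging).
#' @param groups A `group_assignment` from [median_split()].
#' @param n_perm Permutations per ANOVA (default 999).
#' @param seed Optional integer seed.
#' @param scheme Permutation scheme, see [perm_anova_2x2()].
#' @return Tibble: scale, window, band, effect, F_obs, df1, df2, p_perm.
#' @export
group_scale_anova <- function(scale_table, groups, n_perm = 999,
                              seed = NULL, scheme = "manly") {
  stopifnot(inherits(groups, "group_assignment"))
  if (!is.null(seed)) set.seed(seed)
  tab <- dplyr::inner_join(scale_table, groups$assignment,
                           by = "subject_id")
  cells <- unique(tab[, c("scale", "window", "band")])
  out <- list()
  for (k in seq_len(nrow(cells))) {
    sub <- tab[tab$scale == cells$scale[k] &
                 tab$window == cells$window[k] &
                 tab$band == cells$band[k], ]
    df <- data.frame(subject = sub$subject_id, group = sub$group,
                     hand = sub$condition, value = sub$mean_plv)
    res <- perm_anova_2x2(df, n_perm = n_perm, scheme = scheme)
    res$scale <- cells$scale[k]
    res$window <- cells$window[k]
    res$band <- cells$band[k]
    out[[k]] <- res
  }
  dplyr::bind_rows(out)[, c("scale", "window", "band", "effect",
                            "F_obs", "df1", "df2", "p_perm", "n_perm")]
}
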