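# Subcortical ANCOVA with FDR across structures and Bonferroni post-hoc
# pairwise contrasts; closed-form tests on printed summary statistics; and
# the forward-inference binomial kernel for functional decoding.

#' Subcortical ANCOVA with FDR and Bonferroni post-hoc tests
#'
#' For each structure fits `volume ~ group + covariates` by OLS and tests
#' the group factor with a partial F test; raw p-values are
#' Benjamini-Hochberg adjusted across structures.  For structures passing
#' FDR < `fdr_alpha`, all three pairwise group contrasts (adjusted means
#' from the same model) are tested and Bonferroni-corrected
#' (`p_bonf = min(1, 3 p)`).
#'
#' @param dataset a `morphometry_dataset` containing all three groups
#'   (each n >= 3).
#' @param covariates metadata columns to adjust for (default age + sex; the
#'   covariate set of the published analysis is unstated, so this is a
#'   documented default, and `eTIV` is accepted if present).
#' @param structures volume columns to analyse (default: all).
#' @param fdr_alpha FDR level gating the post-hoc tests (default 0.05).
#' @return a `posthoc_table` data.frame: one row per structure with `F`,
#'   `p_raw`, `p_fdr`, and Bonferroni-adjusted pairwise p-values and
#'   directions (`TD-ET`, `TD-HC`, `ET-HC`; NA when the structure fails
#'   FDR).
#' @export
subcortical_ancova <- function(dataset, covariates = c("age", "sex"),
                               structures = NULL, fdr_alpha = 0.05) {
  meta <- dataset$subjects
  tab <- table(meta$group)
  if (length(tab[tab > 0]) < 3 || any(tab < 3)) {
    stop_fmt("ANCOVA needs all three groups with n >= 3 (got TD %d / ET %d / HC %d)",
             tab["TD"], tab["ET"], tab["HC"])
  }
  structures <- structures %||% names(dataset$volumes)
  miss <- setdiff(structures, names(dataset$volumes))
  if (length(miss)) {
    stop_fmt("naming error: structure(s) absent from volume table: %s",
             paste(miss, collapse = ", "))
  }
  Xc <- matrix(1, nrow(meta), 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    col <- meta[[cv]]
    if (cv == "sex") col <- as.numeric(col == "M")
    Xc <- cbind(Xc, col)
  }
  G <- cbind(groupET = as.numeric(meta$group == "ET"),
             groupHC = as.numeric(meta$group == "HC"))
  Xfull <- cbind(Xc, G)

  fit_one <- function(y) {
    b_full <- qr.solve(Xfull, y)
    r_full <- y - Xfull %*% b_full
    b_red <- qr.solve(Xc, y)
    r_red <- y - Xc %*% b_red
    df2 <- length(y) - ncol(Xfull)
    rss_full <- sum(r_full^2); rss_red <- sum(r_red^2)
    Fstat <- ((rss_red - rss_full) / 2) / (rss_full / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
    # pairwise contrasts on adjusted group means (treatment coding: TD ref)
    XtXi <- chol2inv(chol(crossprod(Xfull)))
    s2 <- rss_full / df2
    iET <- which(colnames(Xfull) == "groupET")
    iHC <- which(colnames(Xfull) == "groupHC")
    contrasts <- list(
      `TD-ET` = {v <- rep(0, ncol(Xfull)); v[iET] <- -1; v},
      `TD-HC` = {v <- rep(0, ncol(Xfull)); v[iHC] <- -1; v},
      `ET-HC` = {v <- rep(0, ncol(Xfull)); v[iET] <- 1; v[iHC] <- -1; v})
    pw <- lapply(contrasts, function(cc) {
      est <- sum(cc * b_full)
      se <- sqrt(s2 * drop(t(cc) %*% XtXi %*% cc))
      tt <- est / se
      list(p = min(1, 3 * 2 * stats::pt(-abs(tt), df2)),  # Bonferroni x3
           direction = if (est > 0) ">" else "<")
    })
    list(F = Fstat, p = p, pw = pw)
  }

  fits <- lapply(structures, function(s) fit_one(dataset$volumes[[s]]))
  p_raw <- vapply(fits, `[[`, numeric(1), "p")
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  rows <- lapply(seq_along(structures), function(i) {
    f <- fits[[i]]
    pass <- p_fdr[i] < fdr_alpha
    data.frame(
      structure = structures[i], F = f$F, p_raw = p_raw[i], p_fdr = p_fdr[i],
      p_TD_ET = if (pass) f$pw$`TD-ET`$p else NA_real_,
      dir_TD_ET = if (pass) f$pw$`TD-ET`$direction else NA_character_,
      p_TD_HC = if (pass) f$pw$`TD-HC`$p else NA_real_,
      dir_TD_HC = if (pass) f$pw$`TD-HC`$direction else NA_character_,
      p_ET_HC = if (pass) f$pw$`ET-HC`$p else NA_real_,
      dir_ET_HC = if (pass) f$pw$`ET-HC`$direction else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_table", class(out))
  out
}

#' Group-comparison tests from printed summary statistics
#'
#' Recomputes demographic-table tests from `(mean, sd, n)` triples alone,
#' using the standard closed forms: Welch or pooled (Student) two-sample t
#' for two groups, or one-way ANOVA for k groups.
#'
#' @param rows a data.frame with columns `variable`, `group`, `mean`, `sd`,
#'   `n` (one row per variable x group).
#' @param test `"welch_t"`, `"student_t"` or `"oneway_anova"`.
#' @return data.frame with one row per variable: `statistic`, `df`, `p`.
#' @export
#' @examples
#' rows <- data.frame(variable = "duration", group = c("TD", "ET"),
#'                    mean = c(9.28, 16.41), sd = c(7.16, 12.48),
#'                    n = c(69, 71))
#' summary_stat_tests(rows, "welch_t")
summary_stat_tests <- function(rows,
                               test = c("welch_t", "student_t",
                                        "oneway_anova")) {
  test <- match.arg(test)
  if (any(rows$n < 2)) stop_fmt("each group needs n >= 2")
  if (any(rows$sd <= 0)) stop_fmt("each group needs sd > 0")
  out <- lapply(split(rows, rows$variable), function(rr) {
    k <- nrow(rr)
    if (test %in% c("welch_t", "student_t")) {
      if (k != 2) stop_fmt("arity error: %s needs exactly 2 groups (variable %s has %d)",
                           test, rr$variable[1], k)
      m <- rr$mean; s <- rr$sd; n <- rr$n
      if (test == "welch_t") {
        se2 <- s[1]^2 / n[1] + s[2]^2 / n[2]
        tt <- (m[1] - m[2]) / sqrt(se2)
        df <- se2^2 / ((s[1]^2 / n[1])^2 / (n[1] - 1) +
                       (s[2]^2 / n[2])^2 / (n[2] - 1))
      } else {
        sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (sum(n) - 2)
        tt <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
        df <- sum(n) - 2
      }
      p <- 2 * stats::pt(-abs(tt), df)
      data.frame(variable = rr$variable[1], statistic = tt, df = df, p = p)
    } else {
      if (k < 2) stop_fmt("arity error: oneway_anova needs >= 2 groups")
      N <- sum(rr$n)
      gm <- sum(rr$n * rr$mean) / N
      ssb <- sum(rr$n * (rr$mean - gm)^2)
      ssw <- sum((rr$n - 1) * rr$sd^2)
      df1 <- k - 1; df2 <- N - k
      Fstat <- (ssb / df1) / (ssw / df2)
      p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
      data.frame(variable = rr$variable[1], statistic = Fstat, df = df2,
                 p = p)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Forward-inference binomial test over behavioural domains
#'
#' For each domain with `k` activations out of `n` experiments, tests
#' whether the activation probability exceeds the database-wide base rate
#' with a one-sided exact binomial tail `P(X >= k)`, then adjusts across
#' domains by Benjamini-Hochberg.
#'
#' @param activation_counts data.frame with columns `domain`, `k`, `n`.
#' @param base_rate overall activation probability in (0, 1).
#' @return data.frame with per-domain `p` and `p_fdr`.
#' @export
forward_inference_binomial <- function(activation_counts, base_rate) {
  ac <- activation_counts
  if (base_rate <= 0 || base_rate >= 1) stop_fmt("base_rate must be in (0, 1)")
  if (any(ac$k < 0 | ac$k > ac$n)) {
    stop_fmt("validation error: need 0 <= k <= n for every domain")
  }
  p <- stats::pbinom(ac$k - 1, ac$n, base_rate, lower.tail = FALSE)
  data.frame(domain = ac$domain, k = ac$k, n = ac$n, p = p,
             p_fdr = stats::p.adjust(p, method = "BH"))
}
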