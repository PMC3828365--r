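#' Age of first beta detection
#'
#' The beta-onset age of a mouse is the age of the first session in which a
#' beta peak was detected. No persistence across later sessions is required:
#' a detection followed by a non-detection still dates onset at the first
#' detection.
#'
#' @param age_weeks Strictly increasing session ages in weeks.
#' @param beta_present Logical vector, one flag per session.
#'
#' @return The onset age in weeks, or `NA_real_` if beta was never detected.
#' @export
beta_onset_age <- function(age_weeks, beta_present) {
  if (!length(age_weeks))
    stop_betasleep("no sessions given", "betasleep_input_size_error")
  if (length(age_weeks) != length(beta_present))
    stop_betasleep("age_weeks and beta_present must have equal length",
                   "betasleep_alignment_error")
  if (length(age_weeks) > 1 && any(diff(age_weeks) <= 0))
    stop_betasleep("session ages must be strictly increasing",
                   "betasleep_format_error")
  i <- match(TRUE, as.logical(beta_present))
  if (is.na(i)) NA_real_ else age_weeks[i]
}

#' Beta-onset versus clasping-onset precedence
#'
#' Joins per-mouse beta-onset ages with hindlimb-clasping records (clasping
#' onset = first observation age with clasping; `NA` if never observed) and
#' summarizes the precedence `clasp_onset - beta_onset` in weeks: positive
#' when the oscillation appeared first. Mice whose onsets tie are counted as
#' neither beta-first nor clasp-first.
#'
#' @param onsets Data frame with columns `mouse_id`, `beta_onset_weeks`
#'   (`NA` allowed for mice without detection).
#' @param clasping Data frame of clasping observations with columns
#'   `mouse_id`, `age_weeks`, `clasp` (see [clasping_record()]). Every mouse
#'   with a beta onset must appear here.
#'
#' @return An object of class `precedence_summary`: `per_mouse` data frame
#'   (`mouse_id`, `beta_onset_weeks`, `clasp_onset_weeks`,
#'   `precedence_weeks`), `mean`, `sem`, `n`, `n_beta_first`,
#'   `n_clasp_first`.
#' @export
precedence_summary <- function(onsets, clasping) {
  stopifnot(all(c("mouse_id", "beta_onset_weeks") %in% names(onsets)),
            all(c("mouse_id", "age_weeks", "clasp") %in% names(clasping)))
  with_beta <- onsets$mouse_id[!is.na(onsets$beta_onset_weeks)]
  missing <- setdiff(with_beta, clasping$mouse_id)
  if (length(missing))
    stop_betasleep(paste0("mice missing from the clasping table: ",
                          paste(missing, collapse = ", ")),
                   "betasleep_join_error")
  clasp_onset <- vapply(onsets$mouse_id, function(id) {
    obs <- clasping[clasping$mouse_id == id, , drop = FALSE]
    if (!nrow(obs)) return(NA_real_)
    hit <- obs$age_weeks[obs$clasp]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  per <- data.frame(mouse_id = onsets$mouse_id,
                    beta_onset_weeks = onsets$beta_onset_weeks,
                    clasp_onset_weeks = clasp_onset)
  per$precedence_weeks <- per$clasp_onset_weeks - per$beta_onset_weeks
  both <- per$precedence_weeks[!is.na(per$precedence_weeks)]
  n <- length(both)
  structure(list(
    per_mouse = per,
    mean = if (n) mean(both) else NA_real_,
    sem = if (n > 1) sd(both) / sqrt(n) else NA_real_,
    n = n,
    n_beta_first = sum(both > 0),
    n_clasp_first = sum(both < 0)),
    class = "precedence_summary")
}

#' @export
print.precedence_summary <- function(x, ...) {
  cat(sprintf(
    "<precedence_summary> n = %d, mean %.2f wk (SEM %.2f); beta first in %d, clasp first in %d\n",
    x$n, x$mean, x$sem, x$n_beta_first, x$n_clasp_first))
  invisible(x)
}

#' Pearson chi-square test on a 2 x 2 contingency table
#'
#' Computed directly from the Pearson formula without continuity correction,
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, with the p-value from the chi-square
#' distribution on 1 degree of freedom. The uncorrected statistic is the
#' standard choice for genotype-proportion comparisons of this kind (a
#' 10-of-10 versus 0-of-8 split gives exactly 18).
#'
#' @param counts 2 x 2 numeric matrix of non-negative counts with positive
#'   row and column margins.
#'
#' @return List with `statistic`, `df` (= 1) and `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0))
    stop_betasleep("counts must be a 2 x 2 matrix of non-negative counts",
                   "betasleep_format_error")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_betasleep("all row and column margins must be positive",
                   "betasleep_degenerate_table_error")
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  n <- sum(counts)
  stat <- n * (a * d - b * c)^2 /
    (prod(rowSums(counts)) * prod(colSums(counts)))
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `values ~ factor_a * factor_b` by least squares and reports Type II
#' sums of squares (each main effect adjusted for the other, the interaction
#' adjusted for both mains), which coincide with Type I and Type III on
#' balanced designs and remain well-defined on the unbalanced cell counts
#' that longitudinal cohorts produce. Within-subject correlation is not
#' modeled; both factors are treated as fixed.
#'
#' @param values Numeric response (e.g. summed beta band power).
#' @param factor_a,factor_b Factors (coerced) with at least 2 levels each;
#'   every cell of the cross-classification must be non-empty.
#' @param names_ab Length-2 character vector naming the factors in the
#'   output (default `c("A", "B")`).
#'
#' @return Data frame with one row per term (`A`, `B`, `A:B`): `term`,
#'   `df1`, `df2`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          names_ab = c("A", "B")) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop_betasleep("both factors need at least 2 levels",
                   "betasleep_design_error")
  if (length(values) != length(a) || length(values) != length(b))
    stop_betasleep("values and factors must have equal length",
                   "betasleep_alignment_error")
  if (any(table(a, b) == 0))
    stop_betasleep("empty cell: interaction model is not estimable",
                   "betasleep_design_error")
  dat <- data.frame(y = values, A = a, B = b)
  terms_out <- c(names_ab, paste(names_ab, collapse = ":"))
  fit <- lm(y ~ A * B, data = dat)
  df2 <- df.residual(fit)
  if (var(values) < .Machine$double.eps) {
    # no variance anywhere: all F are 0 by convention
    df1 <- c(nlevels(a) - 1L, nlevels(b) - 1L,
             (nlevels(a) - 1L) * (nlevels(b) - 1L))
    return(data.frame(term = terms_out, df1 = df1, df2 = df2,
                      F = 0, p = 1))
  }
  tab <- car::Anova(fit, type = 2)
  rows <- c("A", "B", "A:B")
  data.frame(term = terms_out,
             df1 = tab[rows, "Df"],
             df2 = df2,
             F = tab[rows, "F value"],
             p = tab[rows, "Pr(>F)"])
}
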