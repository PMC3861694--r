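#' Aggregate localization results into a barycenter table
#'
#' One row per contraction: subject, task, force level (%MVC) and the
#' normalized barycenter coordinates X (medio-lateral, fraction of forearm
#' circumference) and Y (proximal-distal, fraction of forearm length). This
#' table is the input of the statistics layer.
#'
#' @param results list of [LocalizationResult-class] objects whose metadata
#'   carries \code{subject}, \code{task} and \code{levelPctMVC}.
#' @return data.frame with columns \code{subject}, \code{task},
#'   \code{level_pct_mvc}, \code{X}, \code{Y}.
#' @export
buildBarycenterTable <- function(results) {
  cols <- c("subject", "task", "level_pct_mvc", "X", "Y")
  if (length(results) == 0L) {
    out <- data.frame(subject = character(), task = character(),
                      level_pct_mvc = numeric(), X = numeric(),
                      Y = numeric())
    return(out)
  }
  rows <- lapply(results, function(r) {
    m <- r@meta
    if (is.null(m$subject) || is.null(m$task) || is.null(m$levelPctMVC))
      stop("result metadata must carry subject, task and levelPctMVC",
           call. = FALSE)
    if (!all(is.finite(r@barycenterNorm)))
      stop("normalized barycenter missing: anatomy metadata required",
           call. = FALSE)
    data.frame(subject = as.character(m$subject),
               task = as.character(m$task),
               level_pct_mvc = as.numeric(m$levelPctMVC),
               X = r@barycenterNorm[1], Y = r@barycenterNorm[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- paste(out$subject, out$task, out$level_pct_mvc, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, task, level) rows", call. = FALSE)
  out[cols]
}

.checkBalanced <- function(f1, f2, extra = NULL) {
  tab <- if (is.null(extra)) table(f1, f2) else table(f1, f2, extra)
  if (any(tab != 1L))
    stop("design must be balanced with one observation per cell; ",
         "filter the table (e.g. to a single force level) first",
         call. = FALSE)
}

.anovaTable <- function(fit, response) {
  s <- stats::anova(fit)
  terms <- rownames(s)
  data.frame(response = response,
             term = sub("^Residuals$", "residual", trimws(terms)),
             df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
             F = s$`F value`, p = s$`Pr(>F)`)
}

#' Two-way fixed-effects ANOVA on normalized barycenters
#'
#' Tests the effects of subject and task (direction of force) on one
#' barycenter coordinate, with one observation per subject x task cell (so
#' the main-effects model is the saturated one and no interaction can be
#' estimated). Both factors are treated as fixed effects.
#'
#' @param table a barycenter table from [buildBarycenterTable()], restricted
#'   to a single force level.
#' @param response \code{"X"} or \code{"Y"}.
#' @return data.frame with one row per term (\code{subject}, \code{task},
#'   \code{residual}): degrees of freedom, sums of squares, F and p.
#' @export
twowayAnova <- function(table, response = c("X", "Y")) {
  response <- match.arg(response)
  subject <- factor(table$subject)
  task <- factor(table$task)
  if (nlevels(subject) < 2L || nlevels(task) < 2L)
    stop("need at least 2 subjects and 2 tasks", call. = FALSE)
  .checkBalanced(subject, task)
  y <- table[[response]]
  fit <- stats::aov(y ~ subject + task)
  .anovaTable(fit, response)
}

#' Three-way fixed-effects ANOVA on normalized barycenters
#'
#' Tests the effects of subject, force direction (task) and force level
#' (%MVC) on one barycenter coordinate; main effects only, with one
#' observation per subject x task x level cell.
#'
#' @param table a barycenter table covering the force-tracked tasks at every
#'   level.
#' @param response \code{"X"} or \code{"Y"}.
#' @return data.frame with one row per term (\code{subject}, \code{task},
#'   \code{level}, \code{residual}).
#' @export
threewayAnova <- function(table, response = c("X", "Y")) {
  response <- match.arg(response)
  subject <- factor(table$subject)
  task <- factor(table$task)
  level <- factor(table$level_pct_mvc)
  if (nlevels(subject) < 2L || nlevels(task) < 2L || nlevels(level) < 2L)
    stop("need at least 2 levels of each factor", call. = FALSE)
  .checkBalanced(subject, task, level)
  y <- table[[response]]
  fit <- stats::aov(y ~ subject + task + level)
  .anovaTable(fit, response)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Step-down Sidak procedure: the m p-values are sorted ascending and the
#' i-th smallest is adjusted to \code{1 - (1 - p_(i))^(m - i + 1)}, with a
#' running maximum enforcing monotonicity; hypotheses are rejected while the
#' adjusted p-value stays at or below \code{alpha}. Uniformly (slightly) more
#' powerful than Holm's Bonferroni-based step-down under independence.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @param alpha family significance level (default 0.05).
#' @return data.frame in the input order: \code{p}, \code{p_adjusted},
#'   \code{reject}.
#' @examples
#' holmSidak(c(0.001, 0.02, 0.04))
#' @export
holmSidak <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(data.frame(p = numeric(), p_adjusted = numeric(),
                      reject = logical()))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- data.frame(p = p, p_adjusted = NA_real_, reject = NA)
  out$p_adjusted[ord] <- adj
  out$reject <- out$p_adjusted <= alpha
  out
}

#' Pairwise task discrimination on each barycenter axis
#'
#' For every unordered pair of tasks and each normalized coordinate (X:
#' medio-lateral, Y: proximal-distal), tests whether the active-region
#' positions of the two contractions can be distinguished. The comparisons
#' use the pooled residual variance of the two-way (subject + task) ANOVA on
#' that axis, and the family of all pairs on one axis is corrected with
#' [holmSidak()].
#'
#' @param table a barycenter table with one row per subject x task (a single
#'   force level).
#' @param alpha family significance level (default 0.05).
#' @return data.frame with one row per pair and axis: \code{task1},
#'   \code{task2}, \code{axis}, \code{diff} (difference of task means),
#'   \code{t}, \code{df}, \code{p}, \code{p_adjusted}, \code{separable}.
#' @export
pairwiseDiscrimination <- function(table, alpha = 0.05) {
  subject <- factor(table$subject)
  task <- factor(table$task)
  if (nlevels(task) < 2L)
    stop("need at least 2 tasks", call. = FALSE)
  .checkBalanced(subject, task)
  tasks <- levels(task)
  pairs <- utils::combn(tasks, 2)
  out <- list()
  for (axis in c("X", "Y")) {
    y <- table[[axis]]
    fit <- stats::aov(y ~ subject + task)
    s <- stats::anova(fit)
    mse <- s["Residuals", "Mean Sq"]
    dfres <- s["Residuals", "Df"]
    means <- tapply(y, task, mean)
    ns <- tapply(y, task, length)
    d <- means[pairs[1, ]] - means[pairs[2, ]]
    se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    tval <- as.numeric(d / se)
    pval <- 2 * stats::pt(-abs(tval), dfres)
    hs <- holmSidak(pval, alpha = alpha)
    out[[axis]] <- data.frame(
      task1 = pairs[1, ], task2 = pairs[2, ], axis = axis,
      diff = as.numeric(d), t = tval, df = dfres, p = pval,
      p_adjusted = hs$p_adjusted, separable = hs$reject)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
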