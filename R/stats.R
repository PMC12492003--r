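# Group comparison of per-oocyte permeabilities: one-way ANOVA followed by
# Holm-Sidak, Tukey or Dunnett post-hoc tests, with the significance tiers
# used in oocyte-assay figures (* 0.05, ** 0.01, *** 0.001, **** 0.0001).

significanceTier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 5e-2, "*", "ns"))))
}

# Step-down Sidak adjustment (Holm's sequential scheme with the Sidak
# 1-(1-p)^k correction at each step), monotonized.
holmSidakAdjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare permeability groups by ANOVA plus a post-hoc test
#'
#' One-way ANOVA across constructs, followed by the chosen multiple
#' comparison: \code{holm_sidak} (each construct vs the control,
#' pooled-variance t statistics with step-down Sidak adjustment),
#' \code{dunnett} (vs control, via \pkg{multcomp}), or \code{tukey} (all
#' pairwise, via \code{\link[stats]{TukeyHSD}}; rows involving the control
#' are flagged).
#'
#' @param values numeric vector of per-oocyte values (e.g. P_water, cm/s).
#' @param groups factor/character of the construct of each oocyte.
#' @param controlId the control construct (e.g. water-injected oocytes).
#' @param method "holm_sidak", "tukey" or "dunnett".
#' @return List: \code{anova_F}, \code{anova_p}, \code{method},
#'   \code{comparisons} (data frame: comparison, estimate, p_adj, tier),
#'   \code{constant_data} (TRUE when all groups are identical, making the
#'   F test degenerate).
#' @export
compareGroups <- function(values, groups,
                          controlId = "control",
                          method = c("holm_sidak", "tukey", "dunnett")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L))
    stop(sprintf("every group needs n >= 2 (offending: %s)",
                 paste(names(tab)[tab < 2L], collapse = ", ")))
  if (!controlId %in% groups && method != "tukey")
    stop(sprintf("control group '%s' not present", controlId))
  g <- factor(groups)
  constant <- stats::var(values) < .Machine$double.eps * max(1, mean(values)^2)
  if (constant) {
    return(list(anova_F = 0, anova_p = 1, method = method,
                comparisons = data.frame(comparison = character(0),
                                         estimate = numeric(0),
                                         p_adj = numeric(0),
                                         tier = character(0)),
                constant_data = TRUE))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  Fv <- an[1, "F value"]; pv <- an[1, "Pr(>F)"]
  mse <- an[2, "Mean Sq"]; dfr <- an[2, "Df"]
  if (method == "holm_sidak") {
    others <- setdiff(levels(g), controlId)
    est <- p0 <- numeric(length(others))
    for (i in seq_along(others)) {
      a <- values[g == others[i]]; b <- values[g == controlId]
      est[i] <- mean(a) - mean(b)
      tstat <- est[i] / sqrt(mse * (1 / length(a) + 1 / length(b)))
      p0[i] <- 2 * stats::pt(-abs(tstat), dfr)
    }
    cmp <- data.frame(comparison = paste(others, "vs", controlId),
                      estimate = est, p_adj = holmSidakAdjust(p0))
  } else if (method == "dunnett") {
    d <- data.frame(y = values, g = stats::relevel(g, ref = controlId))
    gl <- multcomp::glht(stats::aov(y ~ g, data = d),
                         linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    cmp <- data.frame(
      comparison = sub(" - ", " vs ", names(sm$test$coefficients)),
      estimate = as.numeric(sm$test$coefficients),
      p_adj = as.numeric(sm$test$pvalues))
  } else {
    tk <- stats::TukeyHSD(fit)$g
    cmp <- data.frame(comparison = sub("-", " vs ", rownames(tk)),
                      estimate = tk[, "diff"], p_adj = tk[, "p adj"])
  }
  cmp$tier <- significanceTier(cmp$p_adj)
  rownames(cmp) <- NULL
  list(anova_F = Fv, anova_p = pv, method = method,
       comparisons = cmp, constant_data = FALSE)
}
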