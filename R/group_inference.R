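default_covariates <- c("age", "sex", "education", "mean_fd")

# Validated design matrices for the covariate-adjusted group model.
# Covariates that are constant (or collinear) in the sample are dropped
# with a warning rather than producing a singular fit.
build_designs <- function(pheno, covariates) {
  pheno$group <- factor(pheno$group)
  covariates <- intersect(covariates, names(pheno))
  keep <- character(0)
  for (cv in covariates) {
    v <- pheno[[cv]]
    if (anyNA(v)) stop("covariate '", cv, "' has missing values")
    n_distinct <- length(unique(v))
    if (n_distinct < 2L) {
      warning("dropping covariate '", cv, "': constant within the sample")
    } else {
      keep <- c(keep, cv)
    }
  }
  form_red <- if (length(keep))
    stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  else ~1
  form_full <- stats::as.formula(
    paste("~ group", if (length(keep))
      paste("+", paste(keep, collapse = " + ")) else ""))
  x_full <- stats::model.matrix(form_full, pheno)
  x_red <- stats::model.matrix(form_red, pheno)
  qr_full <- qr(x_full)
  if (qr_full$rank < ncol(x_full)) {
    dropped <- colnames(x_full)[qr_full$pivot[(qr_full$rank + 1):ncol(x_full)]]
    bad_cov <- setdiff(dropped, grep("^group", colnames(x_full), value = TRUE))
    if (length(bad_cov) == 0L)
      stop("group factor is confounded with the covariates; design singular")
    warning("dropping collinear design column(s): ",
            paste(bad_cov, collapse = ", "))
    x_full <- x_full[, setdiff(colnames(x_full), bad_cov), drop = FALSE]
    x_red <- x_red[, setdiff(colnames(x_red), bad_cov), drop = FALSE]
    qr_full <- qr(x_full)
  }
  list(full = x_full, red = x_red, qr_full = qr_full, qr_red = qr(x_red),
       covariates = keep)
}

#' Node-wise covariate-adjusted ANOVA on degree centrality
#'
#' Per node, fits the linear model DC ~ group + age + sex + education +
#' mean_fd and tests the group factor with a partial F test (ANCOVA-style
#' adjustment). P-values are Bonferroni-corrected across the tested
#' nodes.
#'
#' @param dc subjects x nodes matrix (a `dc_table`), row names matching
#'   `pheno$subject_id`.
#' @param pheno data.frame with columns subject_id, group and the
#'   covariates; exactly three group levels, at least two subjects each.
#' @param alpha significance level after correction (default 0.05).
#' @param covariates covariate column names (default age, sex, education,
#'   mean_fd).
#' @return data.frame: node, f_statistic, p_raw, p_bonf, significant.
#' @export
nodewise_anova <- function(dc, pheno, alpha = 0.05,
                           covariates = default_covariates) {
  pheno <- align_pheno(dc, pheno)
  if (nlevels(factor(pheno$group)) != 3L)
    stop("nodewise_anova expects exactly three group levels")
  if (any(table(pheno$group) < 2L)) stop("need at least 2 subjects per group")
  des <- build_designs(pheno, covariates)
  y <- as.matrix(dc)
  rss_full <- colSums(qr.resid(des$qr_full, y)^2)
  rss_red <- colSums(qr.resid(des$qr_red, y)^2)
  df1 <- des$qr_full$rank - des$qr_red$rank
  df2 <- nrow(y) - des$qr_full$rank
  if (df1 < 1L || df2 < 1L) stop("insufficient degrees of freedom")
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  # constant DC across subjects: 0/0 -> no group effect by convention
  degenerate <- rss_full <= 1e-10 * pmax(colSums(y^2), 1)
  f[degenerate & (rss_red - rss_full) <= 1e-8] <- 0
  f[f < 0] <- 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p_bonf <- pmin(1, p * ncol(y))
  data.frame(node = colnames(y), f_statistic = f, p_raw = p,
             p_bonf = p_bonf, significant = p_bonf < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

align_pheno <- function(dc, pheno) {
  if (!is.null(rownames(dc)) && "subject_id" %in% names(pheno)) {
    missing <- setdiff(rownames(dc), pheno$subject_id)
    if (length(missing))
      stop("phenotype table lacks subject(s): ", paste(missing, collapse = ", "))
    pheno <- pheno[match(rownames(dc), pheno$subject_id), , drop = FALSE]
  } else if (nrow(pheno) != nrow(dc)) {
    stop("phenotype rows do not match DC table rows")
  }
  pheno
}

#' Post-hoc pairwise group comparison at selected nodes
#'
#' Two-group covariate-adjusted comparison (t test of the group
#' coefficient in DC ~ group + covariates) restricted to a node set,
#' typically the ANOVA-significant nodes. Bonferroni correction is over
#' the tested set; the direction records which group has the higher
#' adjusted DC.
#'
#' @param dc subjects x nodes matrix.
#' @param pheno phenotype data.frame (see [nodewise_anova()]).
#' @param pair character vector of the two group labels to compare, e.g.
#'   `c("MDD", "HC")`.
#' @param nodes node labels (or indices) to test.
#' @param alpha significance level (default 0.05).
#' @param covariates covariate column names.
#' @return data.frame: node, t_statistic, p_raw, p_bonf, significant,
#'   direction ("<first> > <second>" or the reverse).
#' @export
posthoc_pairwise <- function(dc, pheno, pair, nodes, alpha = 0.05,
                             covariates = default_covariates) {
  if (length(pair) != 2L) stop("pair must name exactly two groups")
  if (length(nodes) == 0L) {
    message("posthoc_pairwise: empty node set, nothing to test")
    return(data.frame(node = character(0), t_statistic = numeric(0),
                      p_raw = numeric(0), p_bonf = numeric(0),
                      significant = logical(0), direction = character(0)))
  }
  pheno <- align_pheno(dc, pheno)
  sel <- pheno$group %in% pair
  if (sum(pheno$group == pair[1]) < 2L || sum(pheno$group == pair[2]) < 2L)
    stop("both groups need at least 2 subjects")
  ph2 <- droplevels(pheno[sel, , drop = FALSE])
  # reference = second label, so a positive coefficient means pair[1] higher
  ph2$group <- factor(ph2$group, levels = c(pair[2], pair[1]))
  y <- as.matrix(dc)[sel, nodes, drop = FALSE]
  des <- build_designs(ph2, covariates)
  x <- des$full
  gcol <- grep("^group", colnames(x))
  xtx_inv <- chol2inv(chol(crossprod(x)))
  betas <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% betas
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv[gcol, gcol])
  tval <- betas[gcol, ] / se
  tval[se == 0] <- 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p_bonf <- pmin(1, p * length(nodes))
  data.frame(node = colnames(y), t_statistic = tval, p_raw = p,
             p_bonf = p_bonf, significant = p_bonf < alpha,
             direction = ifelse(tval >= 0,
                                paste(pair[1], ">", pair[2]),
                                paste(pair[2], ">", pair[1])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Demographic and clinical group comparisons
#'
#' The standard cohort-description tests: chi-squared on the sex-by-group
#' contingency table, one-way ANOVA on age and education across the three
#' groups, and a two-sample t test on BDI-II scores between the SD and HC
#' groups (the groups for which the score is recorded).
#'
#' @param pheno data.frame with group, age, sex, education and optionally
#'   bdi.
#' @return data.frame: variable, test, statistic, p_value.
#' @export
demographic_tests <- function(pheno) {
  pheno$group <- factor(pheno$group)
  tab <- table(pheno$sex, pheno$group)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected cell count in sex-by-group table; ",
         "use an exact test instead")
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  rows <- list(data.frame(variable = "sex", test = "chi-squared",
                          statistic = unname(chi$statistic),
                          p_value = chi$p.value))
  for (v in c("age", "education")) {
    if (!v %in% names(pheno)) next
    fit <- stats::anova(stats::lm(pheno[[v]] ~ pheno$group))
    rows[[length(rows) + 1L]] <-
      data.frame(variable = v, test = "one-way ANOVA",
                 statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1])
  }
  if ("bdi" %in% names(pheno)) {
    sd_scores <- pheno$bdi[pheno$group == "SD" & !is.na(pheno$bdi)]
    hc_scores <- pheno$bdi[pheno$group == "HC" & !is.na(pheno$bdi)]
    if (length(sd_scores) >= 2L && length(hc_scores) >= 2L) {
      tt <- stats::t.test(sd_scores, hc_scores)
      rows[[length(rows) + 1L]] <-
        data.frame(variable = "bdi", test = "two-sample t",
                   statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
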