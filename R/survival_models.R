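# Survival modelling: median dichotomization of repertoire metrics,
# Kaplan-Meier curves with log-rank tests within phenotype strata, and
# multivariate Cox proportional hazards models adjusted for steroid
# phenotype and tumor stage, with optional chain-interaction covariates.

#' Build a clinical record table
#'
#' Validates the clinical metadata contract: `sample_id`, `phenotype`
#' (LSP/HSP), `stage` (I-IV or NA), `event` (1 = death, 0 = censored) and
#' `os_days` (>= 0).
#'
#' @param df data.frame with the columns above (`vital_status` accepted as
#'   an alias for `event`).
#' @return validated data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if ("vital_status" %in% names(df) && !"event" %in% names(df)) {
    df$event <- df$vital_status
  }
  needed <- c("sample_id", "phenotype", "stage", "event", "os_days")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$phenotype %in% c("LSP", "HSP"))) {
    stop("phenotype must be LSP or HSP")
  }
  if (!all(is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage must be I, II, III, IV or NA")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(df$os_days < 0, na.rm = TRUE)) stop("os_days must be >= 0")
  structure(df[, unique(c(needed, names(df)))], class = c("clinical_table",
                                                          "data.frame"))
}

#' Read a clinical metadata TSV
#'
#' @param path TSV with columns `sample_id, phenotype, stage, vital_status`
#'   (or `event`), `os_days`.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", data.table = FALSE,
                                        na.strings = c("NA", ""),
                                        showProgress = FALSE))
  clinical_table(df)
}

#' Median dichotomization into Low / High
#'
#' Values at or below the within-group median go to `Low`, values strictly
#' above to `High` (ties at the median deterministically Low). `NA` values
#' stay `NA`. When all non-missing values are identical the vector cannot be
#' split: all labels come back `NA` with attribute
#' `not_dichotomizable = TRUE`.
#'
#' @param values numeric vector with at least 2 non-missing entries.
#' @return factor with levels `Low`, `High` (attribute `median` records the
#'   cut).
#' @export
dichotomize_by_median <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop("need >= 2 non-missing values to dichotomize")
  med <- stats::median(obs)
  if (all(obs == obs[1])) {
    out <- factor(rep(NA_character_, length(values)),
                  levels = c("Low", "High"))
    attr(out, "not_dichotomizable") <- TRUE
    attr(out, "median") <- med
    return(out)
  }
  lab <- ifelse(values <= med, "Low", "High")
  out <- factor(lab, levels = c("Low", "High"))
  attr(out, "not_dichotomizable") <- FALSE
  attr(out, "median") <- med
  out
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per stratum plus the standard log-rank
#' chi-square comparing the strata. With a single stratum only the estimate
#' is returned (no test). At-risk counts are reported at `ticks`.
#'
#' @param clinical a [clinical_table()] (or data.frame with `os_days`,
#'   `event`).
#' @param labels vector of stratum labels aligned with `clinical` rows; `NA`
#'   rows are dropped.
#' @param ticks times at which to report the number at risk; default five
#'   equal cuts of follow-up.
#' @return object of class `km_result`: list with `curves` (data.frame:
#'   stratum, time, n_risk, n_event, survival), `at_risk`, `chisq`, `df`,
#'   `p`.
#' @export
km_logrank <- function(clinical, labels, ticks = NULL) {
  keep <- !is.na(labels) & !is.na(clinical$os_days) & !is.na(clinical$event)
  time <- clinical$os_days[keep]
  event <- clinical$event[keep]
  grp <- factor(labels[keep])
  if (length(time) == 0) stop("no usable observations")
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  sm <- summary(fit, censored = TRUE)
  stratum <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time))
             else sub("^grp=", "", as.character(sm$strata))
  curves <- data.frame(stratum = stratum, time = sm$time,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       survival = sm$surv, stringsAsFactors = FALSE)
  if (is.null(ticks)) ticks <- pretty(c(0, max(time)), n = 5)
  at_risk <- do.call(rbind, lapply(levels(grp), function(s) {
    tt <- time[grp == s]
    data.frame(stratum = s, time = ticks,
               n_risk = vapply(ticks, function(tk) sum(tt >= tk), integer(1)),
               stringsAsFactors = FALSE)
  }))
  chisq <- df <- p <- NA_real_
  if (nlevels(grp) >= 2) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ grp)
    chisq <- lr$chisq
    df <- length(lr$n) - 1
    p <- stats::pchisq(lr$chisq, df, lower.tail = FALSE)
  }
  structure(list(curves = curves, at_risk = at_risk, chisq = chisq, df = df,
                 p = p, n = as.integer(table(grp))),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d strata (n = %s); log-rank chisq = %s, p = %s\n",
              length(x$n), paste(x$n, collapse = "/"),
              format(x$chisq, digits = 4), format(x$p, digits = 4)))
  invisible(x)
}

#' Multivariate Cox proportional hazards model
#'
#' Fits overall survival against steroid phenotype (HSP as reference, so the
#' protective LSP effect appears as HR < 1), tumor stage (ordinal I=1..IV=4
#' by default, categorical optional) and any supplied metric covariates.
#' Metric covariates enter on the log2(value+1) scale unless
#' `transform_covariates = FALSE`. Interaction covariates are the
#' element-wise product of the two named transformed columns. Ties are
#' handled by Efron's method; confidence intervals are Wald-based; p-values
#' are BH-adjusted across the reported covariates.
#'
#' @param clinical a [clinical_table()].
#' @param covariates optional data.frame of numeric columns (rownames =
#'   sample ids) such as per-chain abundance or entropy.
#' @param interactions list of length-2 character vectors naming covariate
#'   pairs, e.g. `list(c("IGH", "IGK"))`.
#' @param stage_coding `"ordinal"` (default) or `"categorical"`.
#' @param transform_covariates apply [log2p1()] to the metric covariates.
#' @return object of class `cox_result`: data.frame with `covariate, HR,
#'   ci_lower, ci_upper, p_raw, p_adj`, attributes `n`, `n_events`,
#'   `converged`, `metadata`.
#' @export
cox_multivariate <- function(clinical, covariates = NULL,
                             interactions = list(),
                             stage_coding = c("ordinal", "categorical"),
                             transform_covariates = TRUE) {
  stage_coding <- match.arg(stage_coding)
  if (sum(clinical$event, na.rm = TRUE) == 0) {
    stop("no events: Cox model cannot be fit")
  }
  dat <- data.frame(
    time = clinical$os_days,
    event = clinical$event,
    phenotype = factor(clinical$phenotype, levels = c("HSP", "LSP")),
    stringsAsFactors = FALSE
  )
  if (stage_coding == "ordinal") {
    dat$stage <- as.numeric(factor(clinical$stage,
                                   levels = c("I", "II", "III", "IV")))
  } else {
    dat$stage <- factor(clinical$stage, levels = c("I", "II", "III", "IV"))
  }
  terms <- c("phenotype", "stage")
  degenerate <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    idx <- match(clinical$sample_id, rownames(covariates))
    for (cn in colnames(covariates)) {
      v <- covariates[idx, cn]
      safe <- make.names(cn)
      dat[[safe]] <- if (transform_covariates) log2p1(v) else v
      # a constant covariate carries no hazard information: report HR 1
      # with an uninformative CI instead of letting the fit go singular
      if (stats::sd(dat[[safe]], na.rm = TRUE) == 0) {
        degenerate <- c(degenerate, cn)
      } else {
        terms <- c(terms, safe)
      }
    }
    for (pair in interactions) {
      stopifnot(length(pair) == 2)
      nm <- paste(pair, collapse = ":")
      safe <- make.names(nm)
      dat[[safe]] <- dat[[make.names(pair[1])]] * dat[[make.names(pair[2])]]
      terms <- c(terms, safe)
      names(terms)[length(terms)] <- nm
    }
  }
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = dat, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(form, data = dat, ties = "efron"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    }
  )
  sf <- summary(fit)
  coefs <- sf$coefficients
  ci <- sf$conf.int
  pretty_names <- rownames(coefs)
  pretty_names[pretty_names == "phenotypeLSP"] <- "phenotype LSP (vs HSP)"
  pretty_names <- gsub("^X\\.", "", pretty_names)
  pretty_names <- gsub("\\.\\.?", ":", pretty_names)
  pretty_names <- sub(":$", "", pretty_names)
  out <- data.frame(
    covariate = pretty_names,
    HR = unname(coefs[, "exp(coef)"]),
    ci_lower = unname(ci[, "lower .95"]),
    ci_upper = unname(ci[, "upper .95"]),
    p_raw = unname(coefs[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  if (length(degenerate)) {
    out <- rbind(out, data.frame(
      covariate = degenerate, HR = 1, ci_lower = 0, ci_upper = Inf,
      p_raw = 1, stringsAsFactors = FALSE
    ))
  }
  out$p_adj <- bh_adjust(pmax(.Machine$double.xmin, out$p_raw))
  attr(out, "n") <- sf$n
  attr(out, "n_events") <- sf$nevent
  attr(out, "converged") <- is.null(attr(fit, "fit_warning"))
  attr(out, "diagnostics") <- attr(fit, "fit_warning")
  attr(out, "metadata") <- list(
    ties = "efron", stage_coding = stage_coding,
    phenotype_reference = "HSP",
    covariate_scale = if (transform_covariates) "log2(value+1)" else "raw"
  )
  class(out) <- c("cox_result", "data.frame")
  out
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH (Efron ties): n = %d, events = %d\n",
              attr(x, "n"), attr(x, "n_events")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
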