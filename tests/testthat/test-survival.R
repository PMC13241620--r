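clin <- function(time, event, phenotype = "HSP", stage = "II",
                 ids = NULL) {
  n <- length(time)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  clinical_table(data.frame(
    sample_id = ids, phenotype = rep_len(phenotype, n),
    stage = rep_len(stage, n), event = event, os_days = time,
    stringsAsFactors = FALSE
  ))
}

test_that("clinical_table validates its contract", {
  expect_error(clin(c(1, 2), c(0, 2)), "event")
  expect_error(clin(c(-1, 2), c(0, 1)), "os_days")
  expect_error(clin(c(1, 2), c(0, 1), phenotype = "XX"), "phenotype")
  ok <- clin(c(1, 2), c(0, 1))
  expect_s3_class(ok, "clinical_table")
  # vital_status accepted as event alias
  df <- data.frame(sample_id = "a", phenotype = "LSP", stage = "I",
                   vital_status = 1, os_days = 5)
  expect_equal(clinical_table(df)$event, 1)
})

test_that("dichotomize_by_median sends ties to Low and flags constants", {
  lab <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_equal(as.character(lab), c("Low", "Low", "High", "High"))
  lab2 <- dichotomize_by_median(c(1, 2, 2, 9))
  expect_equal(as.character(lab2), c("Low", "Low", "Low", "High"))
  lab3 <- dichotomize_by_median(c(5, 5, 5))
  expect_true(all(is.na(lab3)))
  expect_true(attr(lab3, "not_dichotomizable"))
  expect_error(dichotomize_by_median(c(1, NA, NA)), ">= 2")
  # NA values stay NA without shifting the median
  lab4 <- dichotomize_by_median(c(1, NA, 3, 4, 2))
  expect_true(is.na(lab4[2]))
  expect_equal(as.character(lab4[-2]), c("Low", "High", "High", "Low"))
})

test_that("KM product-limit estimates match hand computation", {
  # three subjects, all events at 1, 2, 3: S = 2/3, 1/3, 0
  km <- km_logrank(clin(c(1, 2, 3), c(1, 1, 1)), rep("all", 3))
  expect_equal(km$curves$survival, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_true(is.na(km$p))  # single stratum: no test

  # censoring: events at 1 and 3, censored at 2 -> S(1)=3/4, S(3)=3/8
  km2 <- km_logrank(clin(c(1, 2, 3, 4), c(1, 0, 1, 0)), rep("all", 4))
  ev <- km2$curves[km2$curves$n_event == 1, ]
  expect_equal(ev$survival, c(3/4, 3/8), tolerance = 1e-12)

  # all censored: flat curve at 1
  km3 <- km_logrank(clin(c(5, 6, 7), c(0, 0, 0)), rep("all", 3))
  expect_true(all(km3$curves$survival == 1))

  # survival starts at 1 and is non-increasing
  set.seed(3)
  km4 <- km_logrank(clin(rexp(30, 0.01), rbinom(30, 1, 0.7)),
                    rep(c("a", "b"), 15))
  for (s in unique(km4$curves$stratum)) {
    sv <- km4$curves$survival[km4$curves$stratum == s]
    expect_true(all(diff(sv) <= 1e-12))
    expect_lte(sv[1], 1)
  }
})

test_that("log-rank is 0/1 for identical strata and label-swap invariant", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  cl <- clin(rep(time, 2), rep(event, 2))
  lab <- rep(c("A", "B"), each = 6)
  km <- km_logrank(cl, lab)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  set.seed(9)
  cl2 <- clin(rexp(40, 0.01), rbinom(40, 1, 0.6))
  lab2 <- rep(c("A", "B"), 20)
  swapped <- ifelse(lab2 == "A", "B", "A")
  expect_equal(km_logrank(cl2, lab2)$p, km_logrank(cl2, swapped)$p,
               tolerance = 1e-12)
  # at-risk table decreases over the requested ticks
  ar <- km_logrank(cl2, lab2, ticks = c(0, 50, 100))$at_risk
  for (s in c("A", "B")) {
    expect_true(all(diff(ar$n_risk[ar$stratum == s]) <= 0))
  }
})

test_that("cox_multivariate recovers a strong protective phenotype effect", {
  params <- simulation_params(n_lsp = 199, n_hsp = 301,
                              loci = character(0),
                              censor_range = c(4000, 8000))
  set.seed(17)
  cl <- simulate_clinical(params)
  expect_gte(mean(cl$event), 0.6)
  fit <- cox_multivariate(cl)
  ph <- fit[grepl("phenotype", fit$covariate), ]
  expect_gte(ph$HR, 0.05)
  expect_lte(ph$HR, 0.2)
  expect_true(ph$ci_lower <= ph$HR && ph$HR <= ph$ci_upper)
  # stage increases hazard (designed log-HR log(1.6) per step)
  st <- fit[fit$covariate == "stage", ]
  expect_gt(st$HR, 1)
})

test_that("cox_multivariate handles degenerate and duplicated inputs", {
  set.seed(19)
  params <- simulation_params(n_lsp = 40, n_hsp = 60, loci = character(0))
  cl <- simulate_clinical(params)
  cov <- data.frame(null_cov = rep(0, nrow(cl)),
                    row.names = cl$sample_id)
  fit <- cox_multivariate(cl, cov)
  row <- fit[fit$covariate == "null_cov", ]
  expect_equal(row$HR, 1)
  expect_true(row$ci_lower <= 1 && row$ci_upper >= 1)

  # duplicating every subject leaves point estimates essentially unchanged
  # (exactly so under Breslow ties; Efron's correction, the package default,
  # perturbs the duplicated-event weights slightly)
  cl2 <- rbind(as.data.frame(cl), transform(as.data.frame(cl),
                                            sample_id = paste0(sample_id,
                                                               "_b")))
  fit2 <- cox_multivariate(clinical_table(cl2))
  ph1 <- fit[grepl("phenotype", fit$covariate), "HR"]
  ph2 <- fit2[grepl("phenotype", fit2$covariate), "HR"]
  expect_equal(ph1, ph2, tolerance = 0.05)

  # zero events is an error
  cl0 <- clin(c(10, 20, 30), c(0, 0, 0))
  expect_error(cox_multivariate(cl0), "events")
})

test_that("interaction covariates are the product of transformed columns", {
  set.seed(23)
  params <- simulation_params(n_lsp = 60, n_hsp = 90, loci = character(0),
                              censor_range = c(3000, 6000))
  cl <- simulate_clinical(params)
  cov <- data.frame(IGH = rpois(nrow(cl), 50), IGK = rpois(nrow(cl), 40),
                    row.names = cl$sample_id)
  fit <- cox_multivariate(cl, cov, interactions = list(c("IGH", "IGK")))
  expect_true("IGH:IGK" %in% fit$covariate)
  expect_equal(nrow(fit), 5)  # phenotype, stage, IGH, IGK, IGH:IGK
  expect_true(all(fit$ci_lower <= fit$HR & fit$HR <= fit$ci_upper))
  expect_true(all(fit$p_adj >= fit$p_raw - 1e-15))
})

test_that("dichotomized KM on pure noise gives calibrated log-rank p", {
  set.seed(29)
  ps <- replicate(60, {
    cl <- clin(rexp(40, 1 / 500), rbinom(40, 1, 0.8))
    km_logrank(cl, dichotomize_by_median(rnorm(40)))$p
  })
  # roughly uniform: no excess of small p-values
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
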