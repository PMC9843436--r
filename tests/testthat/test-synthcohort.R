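test_that("single-region slide contains only background and its class", {
  sp <- slide_spec(48, 48, list(rect_region("FN_like", 6, 6, 36, 36)),
                   mutant_fraction = 0, seed = 2)
  sl <- generate_slide(sp)
  classes <- attr(sl$labels, "classes")
  present <- classes[sort(unique(as.integer(sl$labels)))]
  expect_setequal(present, c("background", "FN_like"))
})

test_that("generation is a pure function of the spec", {
  sp <- slide_spec(40, 40, list(rect_region("FP_like", 4, 4, 32, 32)),
                   mutant_fraction = 0.3, seed = 77)
  a <- generate_slide(sp)
  b <- generate_slide(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$labels, b$labels)
})

test_that("planted mutant share tracks the requested fraction", {
  sp <- slide_spec(96, 96, list(rect_region("FN_like", 8, 8, 80, 80)),
                   mutant_fraction = 0.4, seed = 5)
  sl <- generate_slide(sp)
  classes <- attr(sl$labels, "classes")
  n_mut <- sum(sl$labels == match("mutant_like", classes))
  n_tumor <- n_mut + sum(sl$labels == match("FN_like", classes))
  expect_equal(n_mut / n_tumor, 0.4, tolerance = 0.05 / 0.4)
  # zero fraction -> exactly zero mutant pixels
  sp0 <- slide_spec(48, 48, list(rect_region("FN_like", 6, 6, 36, 36)),
                    mutant_fraction = 0, seed = 5)
  expect_equal(sum(generate_slide(sp0)$labels ==
                     match("mutant_like", classes)), 0)
})

test_that("overlapping regions and zero-area canvases are rejected", {
  expect_error(slide_spec(0, 10, list()), "positive area")
  sp <- slide_spec(30, 30, list(rect_region("FP_like", 2, 2, 20, 20),
                                rect_region("FN_like", 10, 10, 15, 15)),
                   seed = 1)
  expect_error(generate_slide(sp), "overlap")
})

test_that("texture palette invariants are enforced", {
  expect_true(validate_textures(default_texture_params()))
  bad <- default_texture_params()
  bad$FN_like$base_color <- c(250, 250, 250)  # brighter than glass
  expect_error(validate_textures(bad), "darker than background")
  twin <- default_texture_params()
  twin$FN_like <- twin$FP_like  # indistinguishable local statistics
  twin$FN_like$class_name <- "FN_like"
  expect_error(validate_textures(twin), "margin")
})

test_that("cohort labels, frequencies and survival columns are coherent", {
  sp <- cohort_spec(30, mutant_prevalence = 0.5, seed = 3)
  co <- generate_cohort(sp, render = FALSE)
  tab <- co$table
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$time_years > 0))
  expect_true(all(tab$event %in% 0:1))
  expect_true(all(tab$mutant_fraction[tab$mutant == 0] == 0))
  # 15 +- binomial CI mutant slides
  ci <- qbinom(c(0.005, 0.995), 30, 0.5)
  expect_gte(sum(tab$mutant), ci[1])
  expect_lte(sum(tab$mutant), ci[2])
  # class frequencies within binomial sampling error
  p_fp <- mean(tab$class == "FP_like")
  expect_lt(abs(p_fp - 0.5), 3 * sqrt(0.25 / 30))
})

test_that("uncensored null-coefficient event times have the exponential mean", {
  sp <- cohort_spec(500, mutant_prevalence = 0.5,
                    survival = list(baseline_rate = 0.2,
                                    log_hazard_coefficient = 0,
                                    censoring_rate = 0,
                                    max_followup_years = Inf),
                    seed = 8)
  co <- generate_cohort(sp, render = FALSE)
  # exponential mean 1/0.2 = 5, se = 5/sqrt(500)
  expect_equal(mean(co$table$time_years), 5, tolerance = 2 * (5 / sqrt(500)) / 5)
  expect_true(all(co$table$event == 1))
})

test_that("null coefficient decouples the planted feature from survival", {
  pvals <- vapply(1:20, function(s) {
    sp <- cohort_spec(200, mutant_prevalence = 0.5,
                      survival = list(baseline_rate = 0.2,
                                      log_hazard_coefficient = 0,
                                      censoring_rate = 0.05,
                                      max_followup_years = 20),
                      seed = 100 + s)
    co <- generate_cohort(sp, render = FALSE)
    g <- co$table$mutant
    log_rank_test(co$table$time_years, co$table$event, g)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("positive coefficient plants a negative feature-time association", {
  for (s in 1:3) {
    sp <- cohort_spec(500, mutant_prevalence = 0.5,
                      survival = list(baseline_rate = 0.2,
                                      log_hazard_coefficient = 1.5,
                                      censoring_rate = 0,
                                      max_followup_years = Inf),
                      seed = 200 + s)
    co <- generate_cohort(sp, render = FALSE)
    tau <- cor(co$table$mutant_fraction, co$table$time_years,
               method = "kendall")
    expect_lt(tau, 0)
  }
})

test_that("negative rates are rejected", {
  expect_error(cohort_spec(10, survival = list(baseline_rate = -0.1,
                                               log_hazard_coefficient = 0,
                                               censoring_rate = 0,
                                               max_followup_years = 10)),
               "non-negative")
  expect_error(cohort_spec(10, class_balance = c(FP_like = 0.7)), "sum to 1")
})

test_that("TMA layout produces grouped cores with shared ground truth", {
  sp <- cohort_spec(10, seed = 4)
  tma <- generate_tma(10, 2, 32, sp)
  expect_length(tma, 10)
  expect_equal(sum(lengths(lapply(tma, `[[`, "cores"))), 20)
  for (pat in tma) {
    cls <- vapply(pat$cores, function(cr) {
      classes <- attr(cr$labels, "classes")
      tissue <- setdiff(classes[unique(as.integer(cr$labels))], "background")
      tissue[1]
    }, character(1))
    expect_true(all(cls == pat$class))
  }
  # duplicate cores differ in realization (independent noise)
  expect_false(identical(tma[[1]]$cores[[1]]$image$pixels,
                         tma[[1]]$cores[[2]]$image$pixels))
})

test_that("the duplicate-except-one-quadruplicate layout yields 254 cores", {
  sp <- cohort_spec(10, seed = 6)
  cores_per <- c(rep(2L, 125), 4L)
  tma <- generate_tma(126, cores_per, 16, sp, canvas_px = 20)
  expect_equal(sum(lengths(lapply(tma, `[[`, "cores"))), 254)
  expect_error(generate_tma(5, 2, 40, sp, canvas_px = 32), "exceeds canvas")
  expect_error(generate_tma(5, 0, 16, sp), ">= 1")
})

test_that("label maps survive the PNG round trip", {
  sl <- make_slide("stroma", px = 32, seed = 3)
  path <- tempfile(fileext = ".png")
  write_labelmap_png(sl$labels, path)
  back <- read_labelmap_png(path)
  expect_equal(as.integer(back), as.integer(sl$labels))
  unlink(path)
})
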