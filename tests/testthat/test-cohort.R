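test_that("generation is a pure, seeded function of its arguments", {
  a <- generate_cohort(seed = 7)
  b <- generate_cohort(seed = 7)
  expect_identical(a, b)

  # a polluted global RNG state neither changes the cohort nor is disturbed
  set.seed(123)
  before <- .Random.seed
  c2 <- generate_cohort(seed = 7)
  expect_identical(before, .Random.seed)
  expect_identical(a, c2)

  expect_false(identical(generate_cohort(seed = 8), a))
})

test_that("default cohorts have the experiment's group structure", {
  ch <- generate_cohort(seed = 3)
  expect_equal(unname(table(ch$group)[c("control", "sham", "study")]),
               c(5L, 5L, 12L), ignore_attr = TRUE)
  expect_equal(nrow(ch), 22)
  expect_false(anyDuplicated(ch$id) > 0)
})

test_that("generated values respect every group's published range", {
  params <- default_group_params()
  for (seed in 1:25) {
    ch <- generate_cohort(seed = seed)
    for (g in params$group) {
      sub <- ch[ch$group == g, ]
      p <- params[params$group == g, ]
      expect_true(all(2 * sub$pupil_radius >= p$pupil_diameter_min - 1e-9))
      expect_true(all(2 * sub$pupil_radius <= p$pupil_diameter_max + 1e-9))
      expect_true(all(sub$dada_index >= p$dada_min - 1e-9))
      expect_true(all(sub$dada_index <= p$dada_max + 1e-9))
      expect_true(all(sub$degen_density >= p$degen_min))
      expect_true(all(sub$degen_density <= p$degen_max))
    }
    expect_true(all(ch$latent_severity >= 0 & ch$latent_severity <= 1))
    # generated iris radius encodes the index exactly
    expect_equal(ch$dada_index,
                 (ch$iris_radius^2 - ch$pupil_radius^2) / ch$pupil_radius^2,
                 tolerance = 1e-12)
  }
})

test_that("study-group degeneration percentages realise the n_over80 structure", {
  for (k in c(0L, 3L, 8L, 12L)) {
    ch <- generate_cohort(seed = 11, n_over80 = k)
    st <- ch[ch$group == "study", ]
    expect_equal(sum(st$degen_pct > 80), as.integer(k))
    # the >80% subjects are exactly the k most degenerated
    top <- rank(st$degen_density, ties.method = "first") > (12 - k)
    expect_equal(st$degen_pct > 80, top)
  }
  ch <- generate_cohort(seed = 11)
  expect_true(all(ch$degen_pct[ch$group == "control"] < 15))
  expect_true(all(ch$degen_pct[ch$group == "sham"] >= 30 &
                    ch$degen_pct[ch$group == "sham"] < 60))
})

test_that("generator rejects invalid configuration", {
  p <- default_group_params()
  expect_error(generate_cohort(params = p[p$group != "sham", ]),
               class = "pupilratio_config_error")
  expect_error(generate_cohort(n_over80 = 13, seed = 1),
               class = "pupilratio_domain_error")
  expect_error(generate_cohort(noise_frac = 0.5, seed = 1),
               class = "pupilratio_config_error")
  bad <- p; bad$pupil_diameter_min[1] <- 1e6
  expect_error(generate_cohort(params = bad), class = "pupilratio_config_error")
})

test_that("truncated-normal calibration: large study group hits the printed mean", {
  # 10,000 study-group draws: truncation + range mapping shifts the pupil mean
  # by < 1% from the printed 9989.50 um
  p <- default_group_params()
  p$n[p$group == "study"] <- 10000L
  ch <- generate_cohort(params = p, seed = 42)
  st <- ch[ch$group == "study", ]
  expect_lt(abs(mean(2 * st$pupil_radius) - 9989.50) / 9989.50, 0.01)
  expect_lt(abs(mean(st$degen_density) - 18) / 18, 0.01)
})

test_that("within-study rank fidelity at default noise", {
  rho_pd <- rho_ad <- numeric(50)
  for (s in 1:50) {
    st <- generate_cohort(seed = s)
    st <- st[st$group == "study", ]
    rho_pd[s] <- spearman_rho(2 * st$pupil_radius, st$degen_density)$statistic
    rho_ad[s] <- spearman_rho(st$dada_index, st$degen_density)$statistic
  }
  expect_gte(median(rho_pd), 0.97)
  expect_lte(median(rho_ad), -0.97)
})

test_that("fixed-iris mode derives the index from a drawn anatomy", {
  ch <- generate_cohort(seed = 5, iris_mode = "fixed_iris")
  expect_true(all(ch$iris_radius >= ch$pupil_radius))
  expect_equal(ch$dada_index,
               (ch$iris_radius^2 - ch$pupil_radius^2) / ch$pupil_radius^2,
               tolerance = 1e-12)
  # floating iris cannot reproduce the table-faithful DADA summaries
  expect_false(isTRUE(all.equal(
    mean(ch$dada_index[ch$group == "control"]), 2.32, tolerance = 0.05)))
})

test_that("cohort CSV round-trips through write and read", {
  ch <- generate_cohort(seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, f)
  back <- read_cohort_csv(f)
  expect_equal(nrow(back), 22)
  expect_identical(back$id, ch$id)
  expect_identical(back$group, ch$group)
  for (col in c("pupil_radius", "iris_radius", "dada_index",
                "degen_density", "degen_pct", "latent_severity")) {
    expect_equal(back[[col]], ch[[col]], tolerance = 1e-4)
  }
  # second trip is lossless at the stored precision
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(back, f2)
  expect_identical(readLines(f)[-1] == readLines(f2)[-1], rep(TRUE, 22))
})

test_that("empty cohorts and absent optional fields survive CSV I/O", {
  ch <- generate_cohort(seed = 1)
  empty <- ch[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(empty, f)
  expect_length(readLines(f), 1)   # header only

  df <- make_cohort_df(pupil_diam = c(6000, 9000), group = c("control", "study"),
                       degen = c(3, 18))
  write_cohort_csv(df, f)
  back <- read_cohort_csv(f)
  expect_true(all(is.na(back$iris_radius)))
  expect_true(all(is.na(back$dada_index)))
  expect_true(all(is.na(back$degen_pct)))
})

test_that("cohort CSV validation names the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,pupil_diameter_um,iris_radius_um,degen_density",
               "a,control,6000,4000,3",
               "b,study,9000,2000,18"), f)   # row 2: iris < pupil radius
  expect_error(read_cohort_csv(f), "rows 2")

  writeLines(c("id,group,pupil_diameter_um,degen_density",
               "a,control,6000,3",
               "b,haunted,9000,18"), f)
  expect_error(read_cohort_csv(f), "unknown group")

  writeLines(c("id,group,pupil_diameter_um,iris_radius_um,dada_index,degen_density",
               "a,control,6000,6708.2,3.99999,3"), f)  # index at stored precision -> ok
  expect_silent(read_cohort_csv(f))
  writeLines(c("id,group,pupil_diameter_um,iris_radius_um,dada_index,degen_density",
               "a,control,6000,6708.2,4.2,3"), f)  # disagrees by ~5%
  expect_error(read_cohort_csv(f), "dada_index disagrees")
})

test_that("the shipped YAML defaults reproduce the built-in parameters", {
  f <- system.file("extdata", "group_params_default.yaml", package = "pupilratio")
  p <- read_group_params(f)
  d <- default_group_params()
  p <- p[match(d$group, p$group), names(d)]
  rownames(p) <- NULL
  expect_equal(p, d)
})
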