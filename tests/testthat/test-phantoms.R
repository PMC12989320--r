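test_that("phantom generation is a pure function of the seed", {
  sp <- phantom_spec(seed = 9, shape = c(24, 24, 24), spacing_mm = 2)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$structures$body$values, b$structures$body$values)
  expect_identical(a$structures$targets[[1]]$mask$values,
                   b$structures$targets[[1]]$mask$values)
  expect_identical(vapply(a$beams, function(x) x$gantry_deg, numeric(1)),
                   vapply(b$beams, function(x) x$gantry_deg, numeric(1)))
  c2 <- generate_phantom(phantom_spec(seed = 10, shape = c(24, 24, 24)))
  expect_false(identical(a$structures$body$values, c2$structures$body$values))
})

test_that("SIB phantoms nest the boost strictly inside the primary target", {
  sp <- phantom_spec(seed = 21, shape = c(32, 32, 32), sib = TRUE,
                     prescription_Gy = 70)
  case <- generate_phantom(sp)
  expect_length(case$structures$targets, 2)
  prim <- case$structures$targets[[1]]
  boost <- case$structures$targets[[2]]
  expect_true(boost$prescription_Gy > prim$prescription_Gy)
  expect_equal(boost$prescription_Gy, 70)
  expect_true(all(prim$mask$values[boost$mask$values > 0] == 1))  # boost subset
  expect_lt(sum(boost$mask$values), sum(prim$mask$values))
})

test_that("equispaced beams sit at multiples of 360/n", {
  case <- generate_phantom(phantom_spec(seed = 2, shape = c(16, 16, 16),
                                        n_beams = 7, n_oars = 0))
  angles <- vapply(case$beams, function(b) b$gantry_deg, numeric(1))
  expect_equal(angles, (0:6) * 360 / 7, tolerance = 1e-12)
  expect_equal(angles[2], 51.42857, tolerance = 1e-4)
})

test_that("phantoms satisfy the structural invariants across seeds", {
  for (s in c(3, 14, 159, 2653)) {
    case <- generate_phantom(phantom_spec(seed = s, shape = c(24, 24, 24)))
    body <- case$structures$body$values
    for (t in case$structures$targets)
      expect_true(all(body[t$mask$values > 0] == 1))
    rx <- vapply(case$structures$targets, function(t) t$prescription_Gy, numeric(1))
    expect_true(all(rx >= 4 & rx <= 79.2))
    expect_true(length(case$beams) >= 7 && length(case$beams) <= 25)
    for (o in case$structures$oars) {
      expect_true(all(body[o$mask$values > 0] == 1))
      expect_gt(sum(o$mask$values), 0)
    }
  }
})

test_that("cohort split follows the floor-then-remainder rule", {
  tpl <- phantom_spec(shape = c(12, 12, 12), n_beams = 3, n_oars = 0)
  man <- generate_cohort(10, tpl, seed = 5, label = FALSE)
  expect_equal(as.numeric(table(man$cases$split)[c("train", "val", "test")]),
               c(7, 1, 2))
  man1 <- generate_cohort(1, tpl, seed = 5, label = FALSE)
  expect_equal(man1$cases$split, "train")
  expect_error(generate_cohort(0, tpl), ">= 1")

  # disjoint derived seeds give pairwise distinct cases
  hashes <- vapply(man$bundles, function(cs)
    paste(sum(cs$structures$body$values),
          sum(cs$structures$targets[[1]]$mask$values),
          round(cs$structures$targets[[1]]$prescription_Gy, 6),
          length(cs$beams), collapse = "|"), character(1))
  expect_equal(length(unique(hashes)), length(hashes))
})

test_that("cohorts span the configured beam and prescription ranges", {
  tpl <- phantom_spec(shape = c(8, 8, 8), n_oars = 0)
  specs <- lapply(1:60, function(i) {
    sp <- tpl; sp$seed <- 1000 + i
    cs <- generate_phantom(sp)
    c(nb = length(cs$beams), rx = max_prescription(cs))
  })
  nb <- vapply(specs, `[[`, numeric(1), "nb")
  rx <- vapply(specs, `[[`, numeric(1), "rx")
  expect_lt(min(nb), 10); expect_gt(max(nb), 20)
  expect_lt(min(rx), 20); expect_gt(max(rx), 60)
  expect_true(all(nb >= 7 & nb <= 25))
  expect_true(all(rx >= 4 & rx <= 79.2))
})

test_that("written cohorts round trip from disk", {
  tpl <- phantom_spec(shape = c(12, 12, 12), n_beams = 3, n_oars = 1)
  d <- tempfile()
  man <- generate_cohort(2, tpl, seed = 3, out_dir = d, label = FALSE)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_case(man$cases$dir[1])
  fresh <- generate_phantom({sp <- tpl; sp$seed <- man$cases$seed[1]; sp})
  expect_identical(back$structures$body$values, fresh$structures$body$values)
  expect_length(back$beams, 3)
})

test_that("label doses cover the target and scale with the prescription", {
  sp <- phantom_spec(seed = 31, shape = c(32, 32, 32), n_beams = 7,
                     n_oars = 0, sib = FALSE, prescription_Gy = 20)
  case <- generate_phantom(sp)
  op <- dose_operator(case)
  lab <- make_label_dose(case, objective_config(max_iter = 120), op = op)
  expect_true(all(lab$values >= 0))
  rx <- case$structures$targets[[1]]$prescription_Gy
  expect_lt(max(lab$values), 1.6 * rx)
  d95 <- unname(dose_at_volume(lab, case$structures$targets[[1]]$mask, 95))
  expect_gt(d95 / rx, 0.95); expect_lt(d95 / rx, 1.05)

  # doubling every prescription doubles the label dose (engine linearity +
  # scale-invariant objective)
  case2 <- case
  case2$structures$targets[[1]]$prescription_Gy <- 2 * rx
  lab2 <- make_label_dose(case2, objective_config(max_iter = 120), op = op)
  scale <- max(lab2$values) / max(lab$values)
  expect_equal(scale, 2, tolerance = 0.02)
  expect_lt(sqrt(mean((lab2$values - 2 * lab$values)^2)) / max(lab2$values), 0.02)
})

test_that("degenerate phantom requests fail loudly", {
  expect_error(generate_phantom(phantom_spec(seed = 1, shape = c(16, 16, 16),
                                             target_radius_mm = 40)),
               "target larger than body")
  expect_error(phantom_spec(n_beams = 0), "n_beams")
  # zero beams cannot even form a case
  case <- make_simple_case(n = 12, n_beams = 1)
  expect_error(case_bundle(case$structures, list(), case$model), "at least one beam")
})
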