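test_that("prescription channel is the per-voxel prescription over dp_max", {
  case <- make_simple_case(n = 16, rx = 60)
  enc <- encode_prescription(case$structures)
  expect_equal(enc$dp_max_Gy, 60)
  ptv <- case$structures$targets[[1]]$mask$values
  expect_true(all(enc$channel$values[ptv > 0] == 1))     # binary PTV mask
  expect_true(all(enc$channel$values[ptv == 0] == 0))

  # SIB 70/56: discrete levels {1, 0.8}
  g <- centered_grid(16, 2)
  prim <- mask_from(g, function(cc) rowSums(cc^2) <= 64)
  boost <- mask_from(g, function(cc) rowSums(cc^2) <= 16)
  body <- mask_from(g, function(cc) rowSums(cc^2) <= 196)
  ss <- structure_set(body, list(
    list(name = "P", mask = prim, prescription_Gy = 56),
    list(name = "B", mask = boost, prescription_Gy = 70)))
  enc2 <- encode_prescription(ss)
  expect_equal(sort(unique(as.numeric(enc2$channel$values))), c(0, 0.8, 1))
  expect_equal(enc2$dp_max_Gy, 70)

  # invariance under uniform prescription scaling
  ss3 <- ss
  ss3$targets[[1]]$prescription_Gy <- 112
  ss3$targets[[2]]$prescription_Gy <- 140
  expect_identical(encode_prescription(ss3)$channel$values, enc2$channel$values)
})

test_that("avoidance channel uses the OAR=1 / body=0.1 / outside=0 weighting", {
  case <- make_simple_case(n = 16, oar_center = c(12, 0, 0), oar_r = 5)
  av <- encode_avoidance(case$structures)
  body <- case$structures$body$values
  oar <- case$structures$oars[[1]]$mask$values
  ptv <- case$structures$targets[[1]]$mask$values
  expect_true(all(av$values[oar > 0 & ptv == 0] == 1))
  expect_true(all(av$values[body > 0 & oar == 0] == 0.1))
  expect_true(all(av$values[body == 0] == 0))
  expect_true(all(av$values %in% c(0, 0.1, 1)))

  # no OARs: 0.1 * body everywhere
  case0 <- make_simple_case(n = 16)
  av0 <- encode_avoidance(case0$structures)
  expect_equal(av0$values, 0.1 * case0$structures$body$values)
})

test_that("target/OAR overlap follows the configured priority", {
  # OAR overlapping the PTV
  case <- make_simple_case(n = 16, oar_center = c(6, 0, 0), oar_r = 6)
  ptv <- case$structures$targets[[1]]$mask$values
  oar <- case$structures$oars[[1]]$mask$values
  ov <- ptv > 0 & oar > 0
  expect_gt(sum(ov), 0)
  av_t <- encode_avoidance(case$structures, overlap_policy = "target_priority")
  expect_true(all(av_t$values[ov] == 0.1))  # falls back to body value
  av_o <- encode_avoidance(case$structures, overlap_policy = "oar_priority")
  expect_true(all(av_o$values[ov] == 1))    # relabeled as OAR
  # per-OAR weight override
  av_w <- encode_avoidance(case$structures, weights = c(OAR1 = 0.5),
                           overlap_policy = "oar_priority")
  expect_true(all(av_w$values[oar > 0] == 0.5))
})

test_that("beam trace is invariant to beam duplication and permutation", {
  case <- make_simple_case(n = 16, n_beams = 3)
  tr <- encode_beam_trace(case)
  dup <- case; dup$beams <- c(case$beams, case$beams)
  expect_equal(encode_beam_trace(dup)$values, tr$values, tolerance = 1e-12)
  perm <- case; perm$beams <- case$beams[c(2, 3, 1)]
  expect_equal(encode_beam_trace(perm)$values, tr$values, tolerance = 1e-12)

  single <- case; single$beams <- case$beams[1]
  tr1 <- encode_beam_trace(single)
  ap <- convolve_fluence(conformal_aperture(case$structures$targets[[1]]$mask,
                                            case$beams[[1]], 5,
                                            case$model$fluence_pixel_mm),
                         case$model$kernel_sigma_mm)
  d1 <- fcbb_beam_dose(case, case$beams[[1]], ap)
  expect_equal(tr1$values, d1$values / max(d1$values), tolerance = 1e-12)
})

test_that("an equispaced plan on a centered target peaks at the target", {
  case <- make_simple_case(n = 24, n_beams = 8, target_r = 8)
  tr <- encode_beam_trace(case)
  expect_gt(max(tr$values), 0.5)
  expect_lte(max(tr$values), 1.05)
  peak <- which(tr$values == max(tr$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - 12.5) <= 2.5))  # at/adjacent to the center
})

test_that("channels are functionally independent and share the grid", {
  case <- make_simple_case(n = 16, n_beams = 2, oar_center = c(10, 0, 0))
  st <- build_channel_stack(case)
  expect_true(same_grid(st$prescription, st$avoidance))
  expect_true(same_grid(st$prescription, st$beam_trace))
  expect_equal(max(st$prescription$values), 1)
  st2 <- build_channel_stack(case, weights = c(OAR1 = 0.3))
  expect_identical(st2$prescription$values, st$prescription$values)
  expect_identical(st2$beam_trace$values, st$beam_trace$values)
  expect_false(identical(st2$avoidance$values, st$avoidance$values))
})

test_that("channel-stack invariants hold across random phantoms", {
  for (s in c(101, 202, 303, 404, 505, 606)) {
    case <- generate_phantom(phantom_spec(seed = s, shape = c(16, 16, 16),
                                          beam_range = c(3, 7)))
    st <- build_channel_stack(case)
    expect_true(all(st$prescription$values >= 0 & st$prescription$values <= 1))
    expect_equal(max(st$prescription$values), 1)
    expect_true(all(st$avoidance$values %in% c(0, 0.1, 1)))
    expect_true(all(st$beam_trace$values >= 0))
    expect_lte(max(st$beam_trace$values), 1.05)
    # prescription reaches 1 somewhere inside the top-level target
    top <- which.max(vapply(case$structures$targets,
                            function(t) t$prescription_Gy, numeric(1)))
    tm <- case$structures$targets[[top]]$mask$values
    expect_true(any(st$prescription$values[tm > 0] == 1))
  }
})

test_that("channel stacks round trip through NIfTI + JSON", {
  case <- make_simple_case(n = 12, n_beams = 2)
  st <- build_channel_stack(case)
  d <- tempfile()
  write_channel_stack(st, d)
  back <- read_channel_stack(d)
  expect_equal(back$dp_max_Gy, st$dp_max_Gy)
  expect_identical(back$prescription$values, st$prescription$values)
  expect_identical(back$beam_trace$values, st$beam_trace$values)
})
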