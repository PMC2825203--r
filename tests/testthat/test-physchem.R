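test_that("GRAVY equals scale entries on homopolymers and ignores order", {
  es <- hydropathy_scale("eisenberg")
  for (r in c("A", "R", "N", "D", "C", "G", "I", "K", "W", "Y")) {
    expect_identical(gravy(strrep(r, 12)), unname(es[r]))
  }
  set.seed(3)
  p <- random_protein(40)
  shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(gravy(shuffled), gravy(p))
  # X excluded from numerator and denominator
  expect_identical(gravy("GXG"), unname(es["G"]))
  expect_error(gravy("XXX"), "only X")
})

test_that("molecular weight is additive up to one water per bond", {
  water <- 18.01524
  expect_equal(molecular_weight("G"), 57.0519 + water, tolerance = 1e-6)
  expect_equal(molecular_weight("GA"),
               molecular_weight("G") + molecular_weight("A") - water,
               tolerance = 1e-6)
  set.seed(8)
  for (i in 1:10) {
    p <- random_protein(sample(10:50, 1))
    cut <- sample(2:(nchar(p) - 1), 1)
    expect_equal(molecular_weight(p),
                 molecular_weight(substr(p, 1, cut)) +
                   molecular_weight(substr(p, cut + 1, nchar(p))) - water,
                 tolerance = 1e-8)
  }
  expect_error(molecular_weight("GXG"), "position")
})

test_that("net charge behaves like a titration curve", {
  # no ionisable side chains: termini only
  expect_lt(abs(net_charge(strrep("G", 10), 7)), 1)
  # symmetric ionisable pairs nearly cancel at neutral pH
  expect_lt(abs(net_charge("KKDD", 7)), 0.2)
  # monotone decreasing in pH
  set.seed(4)
  for (i in 1:10) {
    p <- random_protein(30)
    expect_gt(net_charge(p, 1), net_charge(p, 13))
  }
  expect_error(net_charge("GG", 7, pka = "NotATable"), "unknown pKa")
})

test_that("the isoelectric point is the zero of the net charge", {
  set.seed(9)
  for (i in 1:10) {
    p <- random_protein(sample(20:60, 1))
    pi <- isoelectric_point(p)
    expect_lt(abs(net_charge(p, pi)), 0.01)
    # appending a lysine cannot lower the pI
    expect_gte(isoelectric_point(paste0(p, "K")) - pi, -1e-3)
  }
})

test_that("charge-hydropathy coordinates follow their definitions", {
  # poly-I sits at the rescaled Kyte-Doolittle maximum
  expect_equal(uversky_coordinates(strrep("I", 30))$h, 1.0)
  # balanced charge cancels exactly
  expect_identical(uversky_coordinates("KKDDKKDD")$r, 0)
  expect_equal(uversky_coordinates(strrep("K", 20))$r, 1.0)

  # hand-computed truncated-window smoothing on a 7-mer
  p <- "MKDIWGS"
  kd <- hydropathy_scale("kyte-doolittle")
  v <- (kd[strsplit(p, "")[[1]]] + 4.5) / 9
  manual <- mean(c(mean(v[1:3]), mean(v[1:4]), mean(v[1:5]),
                   mean(v[2:6]), mean(v[3:7]), mean(v[4:7]),
                   mean(v[5:7])))
  expect_equal(uversky_coordinates(p, window = 5)$h, unname(manual))

  expect_warning(uversky_coordinates("MKD", window = 5), "window")
})

test_that("r and GRAVY are permutation-invariant; windowed h is not", {
  set.seed(17)
  p <- paste(c(strrep("K", 10), strrep("I", 10)), collapse = "")
  shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(uversky_coordinates(shuffled)$r, uversky_coordinates(p)$r)
  # in the window=1 limit the mean is order-free
  expect_equal(uversky_coordinates(shuffled, window = 1)$h,
               uversky_coordinates(p, window = 1)$h)
  # with smoothing, end truncation makes order matter for this block seq
  expect_false(isTRUE(all.equal(uversky_coordinates(shuffled, window = 5)$h,
                                uversky_coordinates(p, window = 5)$h)))
})

test_that("physchem_profile collects consistent fields", {
  p <- paste0("M", make_lea_like_protein(80, seed = 2))
  prof <- physchem_profile(p)
  expect_identical(prof$length, nchar(p))
  expect_false(prof$has_cys)
  expect_false(prof$has_trp)
  expect_true(prof$mean_scaled_hydropathy >= 0 &&
                prof$mean_scaled_hydropathy <= 1)
  expect_true(prof$mean_net_charge >= 0 && prof$mean_net_charge <= 1)
  expect_equal(prof$gravy, gravy(p))
})
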