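test_that("containment fraction equals brute-force pixel-set arithmetic", {
  dm <- c(40, 40)
  # subset disk -> 1; disjoint -> no candidate; half-overlapping squares -> 0.5
  host_sq <- expand.grid(row = 10:17, col = 10:17)
  dead_sq <- expand.grid(row = 10:17, col = 14:21)
  host <- objects_from_mask(mask_from_coords(host_sq, dm), "viable")[[1]]
  dead <- objects_from_mask(mask_from_coords(dead_sq, dm), "dead")[[1]]
  expect_equal(containment_fraction(dead, host), 0.5)
  expect_equal(containment_fraction(dead, host),
               oracle_containment(dead_sq, host_sq))
  inner <- objects_from_mask(
    mask_from_coords(oracle_disk_coords(13, 13, 3), dm), "dead")[[1]]
  expect_equal(containment_fraction(inner, host), 1.0)
  far <- objects_from_mask(
    mask_from_coords(oracle_disk_coords(33, 33, 3), dm), "dead")[[1]]
  expect_equal(containment_fraction(far, host), 0.0)
  # randomized shapes vs the oracle
  set.seed(42)
  for (i in 1:20) {
    a <- oracle_disk_coords(20 + runif(1, -3, 3), 20 + runif(1, -3, 3),
                            runif(1, 4, 9))
    b <- oracle_disk_coords(20 + runif(1, -6, 6), 20 + runif(1, -6, 6),
                            runif(1, 3, 6))
    oa <- objects_from_mask(mask_from_coords(a, dm), "viable")[[1]]
    ob <- objects_from_mask(mask_from_coords(b, dm), "dead")[[1]]
    expect_equal(containment_fraction(ob, oa), oracle_containment(b, a))
  }
})

test_that("circularity separates disks from bars", {
  dm <- c(60, 60)
  disk <- objects_from_mask(
    mask_from_coords(oracle_disk_coords(30, 30, 20), dm), "dead")[[1]]
  expect_gte(circularity(disk), 0.9)
  bar <- matrix(0L, 10, 40); bar[5, 3:32] <- 1L
  expect_lt(circularity(objects_from_mask(bar, "dead")[[1]]), 0.35)
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  cs <- circularity(objects_from_mask(single, "dead")[[1]])
  expect_true(is.finite(cs) && cs <= 1.0)
})

test_that("crescent score matches brute-force hull enumeration and grows with bite depth", {
  dm <- c(60, 60)
  # convex nucleus scores exactly 0
  disk <- oracle_disk_coords(30, 30, 10)
  expect_equal(crescent_score(coords_to_idx(disk, dm), dm), 0)
  # bitten disks across depths: oracle equality and strict monotonicity
  scores <- c()
  for (depth in c(0.2, 0.4, 0.6)) {
    d <- 10 + 5 - depth * 10
    bite <- oracle_disk_coords(30, 30 + d, 5)
    key <- function(df) paste(df$row, df$col)
    nuc <- disk[!key(disk) %in% key(bite), ]
    s <- crescent_score(coords_to_idx(nuc, dm), dm)
    expect_equal(s, oracle_solidity_deficit(nuc), tolerance = 1e-12)
    scores <- c(scores, s)
  }
  expect_true(all(diff(scores) > 0))
  # randomized bitten shapes vs the oracle
  set.seed(7)
  for (i in 1:20) {
    r1 <- runif(1, 6, 12); r2 <- runif(1, 3, 7); th <- runif(1, 0, 2 * pi)
    d <- r1 + r2 - runif(1, 0.2, 0.8) * r1
    nucd <- oracle_disk_coords(30, 30, r1)
    bite <- oracle_disk_coords(30 + d * cos(th), 30 + d * sin(th), r2)
    key <- function(df) paste(df$row, df$col)
    nuc <- nucd[!key(nucd) %in% key(bite), ]
    expect_equal(crescent_score(coords_to_idx(nuc, dm), dm),
                 oracle_solidity_deficit(nuc), tolerance = 1e-12)
  }
})

test_that("zero-noise planted scenes are recovered exactly with defaults", {
  for (seed in 0:9) {
    sc <- generate_coincubation_scene(recovery_spec(seed, noise_sigma = 0))
    an <- analyze_scene(sc$image)
    r <- evaluate_recovery(an, sc$truth)
    expect_equal(r$precision, 1.0)
    expect_equal(r$recall, 1.0)
  }
})

test_that("accepted events respect thresholds, single assignment, and border exclusion", {
  sc <- generate_coincubation_scene(scene_spec(seed = 21, n_cic = 3))
  an <- analyze_scene(sc$image)
  p <- cic_params()
  acc <- an$events[an$events$accepted, ]
  expect_true(all(acc$containment_fraction >= p$containment_min))
  expect_true(all(acc$circularity >= p$circularity_min))
  expect_true(all(acc$crescent_score >= p$crescent_min))
  expect_equal(anyDuplicated(acc$engulfed_id), 0)
  hosts <- Filter(function(v) v$id %in% acc$host_id, an$viable)
  expect_true(all(!vapply(hosts, function(v) v$border_touching, logical(1))))
})

test_that("partially overlapping dead cells are rejected below the containment cutoff", {
  dm <- c(60, 60)
  host_px <- oracle_disk_coords(30, 25, 14)
  dead_px <- oracle_disk_coords(30, 39, 6)    # straddles the host boundary
  hmask <- mask_from_coords(host_px, dm)
  dmask <- mask_from_coords(dead_px, dm)
  nmask <- mask_from_coords(oracle_disk_coords(30, 20, 5), dm)
  viable <- assign_nuclei(extract_objects(hmask, "viable"),
                          extract_objects(nmask, "nucleus"))
  ev <- detect_cic(viable, extract_objects(dmask, "dead"),
                   extract_objects(nmask, "nucleus"), cic_params())
  expect_equal(nrow(ev), 1)
  expect_lt(ev$containment_fraction, 0.9)
  expect_false(ev$accepted)
  # retained for audit with its scores
  expect_true(is.finite(ev$circularity))
})

test_that("a dead cell inside nested candidate hosts goes to the higher containment", {
  dm <- c(80, 80)
  outer <- oracle_disk_coords(40, 40, 25)
  inner_host <- oracle_disk_coords(40, 35, 14)
  dead <- oracle_disk_coords(40, 30, 5)        # fully in both
  key <- function(df) paste(df$row, df$col)
  # make the outer host miss a sliver of the dead cell so containments differ
  outer <- outer[!key(outer) %in% key(oracle_disk_coords(40, 26, 2)), ]
  vmask <- mask_from_coords(inner_host, dm)
  viable <- extract_objects(vmask, "viable")
  v2 <- objects_from_mask(mask_from_coords(outer, dm, 2L), "viable")
  viable <- structure(c(viable, v2), class = "cic_objects")
  dobj <- extract_objects(mask_from_coords(dead, dm), "dead")
  cf1 <- containment_fraction(dobj[[1]], viable[[1]])
  cf2 <- containment_fraction(dobj[[1]], viable[[2]])
  expect_gt(cf1, cf2)   # fixture sanity
  ev <- suppressWarnings(detect_cic(viable, dobj, list(),
                   cic_params(require_crescent = FALSE, circularity_min = 0)))
  acc <- ev[ev$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$host_id, 1)
})

test_that("lowering the containment cutoff never loses accepted events", {
  sc <- generate_coincubation_scene(scene_spec(seed = 31, n_cic = 3,
                                               n_dead_free = 4))
  an <- analyze_scene(sc$image)
  masks <- an$masks
  viable <- assign_nuclei(extract_objects(masks$green, "viable"),
                          extract_objects(masks$dapi, "nucleus"))
  dead <- extract_objects(masks$red, "dead")
  nuclei <- extract_objects(masks$dapi, "nucleus")
  n_prev <- -1L
  for (cmin in c(0.99, 0.9, 0.5, 0.1)) {
    ev <- detect_cic(viable, dead, nuclei, cic_params(containment_min = cmin))
    n <- sum(ev$accepted)
    if (n_prev >= 0) expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("hosts without an assigned nucleus are rejected unless the crescent is waived", {
  dm <- c(60, 60)
  host <- extract_objects(mask_from_coords(oracle_disk_coords(30, 30, 14), dm),
                          "viable")   # nucleus_id stays NA
  dead <- extract_objects(mask_from_coords(oracle_disk_coords(30, 33, 5), dm),
                          "dead")
  ev <- detect_cic(host, dead, list(), cic_params())
  expect_false(any(ev$accepted))
  expect_warning(
    ev2 <- detect_cic(host, dead, list(), cic_params(require_crescent = FALSE)),
    "no assigned nucleus")
  expect_true(any(ev2$accepted))
})
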