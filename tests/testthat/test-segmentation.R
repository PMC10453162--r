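test_that("disjoint disks segment to one label each at zero noise", {
  sc <- generate_coincubation_scene(scene_spec(seed = 1, noise_sigma = 0,
                                               n_viable_free = 5, n_cic = 2))
  mask <- segment_channel(sc$image$channels$green)
  expect_equal(max(mask), 7)
  expect_equal(sort(unique(as.vector(mask))), 0:7)   # contiguous labels
  # labels partition the foreground: each foreground pixel in exactly one object
  objs <- extract_objects(mask, "viable")
  all_px <- unlist(lapply(objs, function(o) o$pixels))
  expect_equal(anyDuplicated(all_px), 0)
  expect_equal(sort(all_px), which(mask > 0))
})

test_that("blank and constant channels give empty masks, not errors", {
  expect_equal(max(segment_channel(matrix(37L, 40, 40))), 0)
  expect_equal(max(segment_channel(matrix(0L, 40, 40))), 0)
})

test_that("touching disks are split by the watershed when requested", {
  dm <- c(64, 110)
  img <- matrix(10L, dm[1L], dm[2L])
  c1 <- oracle_disk_coords(32, 35, 15); c2 <- oracle_disk_coords(32, 62, 15)
  img[coords_to_idx(c1, dm)] <- 180L
  img[coords_to_idx(c2, dm)] <- 180L
  fused <- segment_channel(img, segmentation_params(split_touching = FALSE))
  expect_equal(max(fused), 1)
  split <- segment_channel(img, segmentation_params(split_touching = TRUE,
                                                    watershed_min_distance_px = 9))
  expect_equal(max(split), 2)
  # each true center falls in a distinct label
  l1 <- split[32, 35]; l2 <- split[32, 62]
  expect_true(l1 > 0 && l2 > 0 && l1 != l2)
})

test_that("components below min_area_px are removed and labels stay contiguous", {
  img <- matrix(10L, 50, 50)
  img[5:6, 5:6] <- 200L          # 4 px speck
  img[20:35, 20:35] <- 200L      # 256 px object
  mask <- segment_channel(img, segmentation_params(min_area_px = 30))
  expect_equal(max(mask), 1)
  expect_equal(sum(mask == 1), 256)
})

test_that("object measurements match brute-force pixel enumeration", {
  # 5x5 square: area 25, centroid at its center (0-based)
  m <- matrix(0L, 20, 20); m[4:8, 6:10] <- 1L
  o <- extract_objects(m, "viable")[[1]]
  expect_equal(o$pixel_count, 25)
  expect_equal(unname(o$centroid), c(5, 7))     # rows 4:8 -> 0-based mean 5
  expect_equal(unname(o$bbox), c(3, 8, 5, 10))  # half-open
  # disk radius 10: area within 5% of pi * 100 and equal to enumeration
  dm <- c(40, 40)
  dc <- oracle_disk_coords(20, 20, 10)
  o2 <- extract_objects(mask_from_coords(dc, dm), "dead")[[1]]
  expect_equal(o2$pixel_count, nrow(dc))
  expect_lt(abs(o2$pixel_count - pi * 100) / (pi * 100), 0.05)
})

test_that("label gaps are tolerated and ids preserved", {
  m <- matrix(0L, 30, 30); m[2:6, 2:6] <- 1L; m[15:22, 15:22] <- 3L
  objs <- extract_objects(m, "viable")
  expect_length(objs, 2)
  expect_equal(vapply(objs, function(o) o$id, numeric(1)), c(1, 3))
  expect_equal(objs[[2]]$pixel_count, 64)
})

test_that("border-touching objects are flagged", {
  m <- matrix(0L, 20, 20); m[1:4, 5:8] <- 1L; m[10:13, 10:13] <- 2L
  objs <- extract_objects(m, "viable")
  expect_true(objs[[1]]$border_touching)
  expect_false(objs[[2]]$border_touching)
})

test_that("nuclei link to the cells containing their centroid", {
  sc <- generate_coincubation_scene(scene_spec(seed = 6, noise_sigma = 0,
                                               n_cic = 2, n_viable_free = 3))
  an <- analyze_scene(sc$image)
  linked <- vapply(an$viable, function(v) v$nucleus_id, numeric(1))
  expect_true(all(!is.na(linked)))          # every planted viable cell has one
  expect_equal(anyDuplicated(linked[!is.na(linked)]), 0)
  # the linked nucleus centroid indeed lies inside the cell
  for (v in an$viable) {
    nu <- an$nuclei[[v$nucleus_id]]
    ctr <- (round(nu$centroid[["col"]])) * nrow(an$masks$green) +
      round(nu$centroid[["row"]]) + 1
    expect_true(ctr %in% v$pixels)
  }
})

test_that("nucleus assignment follows overlap for ambiguous hand-built cases", {
  dm <- c(30, 30)
  # nucleus straddling two hand-made overlapping 'cells' 60/40
  nuc <- oracle_disk_coords(15, 15, 5)
  nmask <- mask_from_coords(nuc, dm)
  nuclei <- extract_objects(nmask, "nucleus")
  cell_a <- expand.grid(row = 5:25, col = 5:18)   # covers centroid, larger share
  cell_b <- expand.grid(row = 5:25, col = 14:25)  # covers centroid, smaller share
  viable <- list(
    structure(list(id = 1L, class = "viable", pixel_count = nrow(cell_a),
                   centroid = c(row = 14, col = 9), perimeter_px = 60,
                   bbox = c(4, 25, 4, 16), border_touching = FALSE,
                   nucleus_id = NA_integer_,
                   pixels = coords_to_idx(cell_a, dm), dim = dm),
              class = "cell_object"),
    structure(list(id = 2L, class = "viable", pixel_count = nrow(cell_b),
                   centroid = c(row = 14, col = 19), perimeter_px = 60,
                   bbox = c(4, 25, 13, 25), border_touching = FALSE,
                   nucleus_id = NA_integer_,
                   pixels = coords_to_idx(cell_b, dm), dim = dm),
              class = "cell_object"))
  class(viable) <- "cic_objects"
  ov_a <- oracle_containment(nuc, cell_a)
  ov_b <- oracle_containment(nuc, cell_b)
  expect_gt(ov_a, ov_b)   # fixture sanity: a genuinely larger overlap
  out <- assign_nuclei(viable, nuclei)
  expect_equal(out[[1]]$nucleus_id, 1L)
  expect_true(is.na(out[[2]]$nucleus_id))
  # a nucleus whose centroid is outside every cell stays unassigned
  far <- extract_objects(mask_from_coords(oracle_disk_coords(27, 27, 2), dm),
                         "nucleus")
  out2 <- assign_nuclei(structure(list(), class = "cic_objects"), far)
  expect_equal(attr(out2, "unassigned_nuclei"), far[[1]]$id)
})
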