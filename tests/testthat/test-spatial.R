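test_that("label expansion matches the brute-force distance transform", {
  m <- matrix(0L, 7, 7)
  m[4, 4] <- 1L
  img <- label_image(m)
  ex <- expand_labels(img, 2)
  # Euclidean disk of radius 2 around one pixel has 13 pixels
  expect_equal(sum(ex == 1), 13)
  expect_equal(unclass(ex), expand_oracle(m, 2), ignore_attr = TRUE)
  # distance 0 is the identity
  expect_equal(unclass(expand_labels(img, 0)), m, ignore_attr = TRUE)
  # random label images match the oracle
  set.seed(8)
  for (r in 1:3) {
    mr <- matrix(0L, 9, 9)
    mr[cbind(sample(9, 3), sample(9, 3))] <- 1:3
    er <- expand_labels(label_image(mr), 1.5)
    expect_equal(unclass(er), expand_oracle(mr, 1.5), ignore_attr = TRUE)
    # segments never merge, original labels unchanged
    expect_setequal(unique(as.vector(er)[as.vector(er) > 0]), 1:3)
    expect_true(all(er[mr > 0] == mr[mr > 0]))
  }
  # micrometre distances honor the pixel size
  img2 <- label_image(m, pixel_size = 0.5)
  expect_equal(sum(expand_labels(img2, 1, units = "um") == 1), 13)
})

test_that("transcript assignment conserves totals and matches lookup", {
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- 1L
  m[3:4, 3:4] <- 2L
  img <- label_image(m, pixel_size = 2)  # image spans 8 x 8 um
  tx <- data.frame(x = c(1, 3, 5, 7, 20, 1),
                   y = c(1, 7, 1, 7, 1, 7),
                   gene = c("a", "a", "b", "a", "a", "b"))
  cm <- assign_transcripts(img, tx)
  # (1,1)->seg1; (3,7)->row4,col2 bg; (5,1)->row1,col3 bg; (7,7)->seg2;
  # (20,1) out of bounds; (1,7)->row4col1 bg
  expect_equal(sum(cm), 2)
  expect_equal(unname(cm["a", "1"]), 1)
  expect_equal(unname(cm["a", "2"]), 1)
  expect_equal(attr(cm, "n_out_of_bounds"), 1)
  expect_equal(sum(cm) + attr(cm, "n_unassigned") +
                 attr(cm, "n_out_of_bounds"), nrow(tx))
  # random data equals a per-transcript lookup oracle
  set.seed(5)
  mr <- matrix(sample(0:3, 100, TRUE), 10, 10)
  imgr <- label_image(mr, pixel_size = 1)
  txr <- data.frame(x = runif(200, 0, 10), y = runif(200, 0, 10),
                    gene = sample(c("g1", "g2"), 200, TRUE))
  cmr <- assign_transcripts(imgr, txr)
  for (k in seq_len(nrow(txr))) {
    lab <- mr[floor(txr$y[k]) + 1, floor(txr$x[k]) + 1]
    if (lab > 0) {
      expect_gte(cmr[txr$gene[k], as.character(lab)], 1)
    }
  }
  oracle_total <- sum(mr[cbind(floor(txr$y) + 1, floor(txr$x) + 1)] > 0)
  expect_equal(sum(cmr), oracle_total)
})

test_that("segment area filter implements the unscaled MAD rule", {
  m <- matrix(0L, 12, 12)
  m[1, 1:10] <- 1L; m[2, 1:10] <- 2L; m[3, 1:10] <- 3L; m[4, 1:10] <- 4L
  m[6:12, 1:10] <- 5L  # area 70 outlier; others area 10
  out <- filter_segments_by_area(label_image(m))
  # median 10, MAD 0 -> cutoff 10; only the big segment goes
  expect_equal(attr(out, "removed"), 5L)
  expect_true(all(out[m == 5] == 0))
  expect_true(all(out[m %in% 1:4] > 0))
  # all-equal areas: nothing removed
  out2 <- filter_segments_by_area(label_image(m * (m <= 4)))
  expect_length(attr(out2, "removed"), 0)
  # naive predicate oracle on random areas
  set.seed(4)
  sizes <- sample(5:40, 12)
  mr <- matrix(0L, 30, 30)
  px <- sample(900, sum(sizes))
  mr[px] <- rep(1:12, sizes)
  areas <- table(mr[mr > 0])
  cut <- median(areas) + 4 * median(abs(areas - median(areas)))
  outr <- filter_segments_by_area(label_image(mr))
  expect_setequal(attr(outr, "removed"),
                  as.integer(names(areas)[areas > cut]))
})

test_that("area annotation uses closed polygon boundaries", {
  poly <- data.frame(area = "sq", group = "distal",
                     x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  cells <- data.frame(x = c(0.5, 1.0, 2.0), y = c(0.5, 0.5, 0.5))
  out <- annotate_areas(cells, poly)
  expect_equal(out$roi, c("sq", "sq", NA))  # edge point is inside
  expect_equal(out$group[1], "distal")
  expect_error(annotate_areas(cells, poly[1:2, ]), "fewer than 3")
  # overlapping polygons: first-listed wins
  poly2 <- rbind(poly,
                 data.frame(area = "sq2", group = "proximal",
                            x = c(0.4, 2, 2, 0.4), y = c(0, 0, 1, 1)))
  expect_warning(out2 <- annotate_areas(cells, poly2), "overlap")
  expect_equal(out2$roi, c("sq", "sq", "sq2"))
  # crossing-number oracle on random points and a random simple polygon
  set.seed(9)
  ang <- sort(runif(7, 0, 2 * pi))
  rad <- runif(7, 0.5, 1)
  polyr <- data.frame(area = "r", group = "g",
                      x = cos(ang) * rad, y = sin(ang) * rad)
  pts <- data.frame(x = runif(300, -1, 1), y = runif(300, -1, 1))
  got <- !is.na(annotate_areas(pts, polyr)$roi)
  crossing <- vapply(seq_len(nrow(pts)), function(k) {
    xj <- polyr$x; yj <- polyr$y
    n <- length(xj); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((yj[i] > pts$y[k]) != (yj[j] > pts$y[k]) &&
          pts$x[k] < (xj[j] - xj[i]) * (pts$y[k] - yj[i]) /
            (yj[j] - yj[i]) + xj[i]) inside <- !inside
      j <- i
    }
    inside
  }, TRUE)
  expect_gte(mean(got == crossing), 0.99)  # boundary-convention slack
})

test_that("radius graph equals the brute-force distance-matrix graph", {
  cells <- data.frame(x = c(0, 5, 20), y = c(0, 0, 0))
  expect_equal(nrow(build_neighbor_graph(cells, 10)), 1)
  expect_equal(build_neighbor_graph(cells, 10)[1, ],
               c(i = 1L, j = 2L))
  # duplicate coordinates connect; ties at exactly the radius do not
  dup <- data.frame(x = c(1, 1, 11), y = c(2, 2, 2))
  e <- build_neighbor_graph(dup, 10)
  expect_equal(nrow(e), 1)
  set.seed(10)
  pts <- data.frame(x = runif(300, 0, 60), y = runif(300, 0, 60))
  got <- build_neighbor_graph(pts, 10, k_cap = 1000)
  got <- got[order(got[, 1], got[, 2]), ]
  d <- as.matrix(dist(pts))
  want <- which(upper.tri(d) & d < 10, arr.ind = TRUE)
  want <- cbind(i = pmin(want[, 1], want[, 2]),
                j = pmax(want[, 1], want[, 2]))
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
  # saturation warns
  crowd <- data.frame(x = runif(50, 0, 3), y = runif(50, 0, 3))
  expect_warning(build_neighbor_graph(crowd, 10, k_cap = 5), "cap")
})

test_that("colocalization test detects planted attraction with sign", {
  att <- data.frame(type_a = "A", type_b = "B", fraction_paired = 0.6,
                    pair_distance = 5, group = "proximal")
  pts <- simulate_point_pattern(c(A = 80, B = 80), roi_size = 200,
                                attraction = att, n_rois = 4, seed = 12)
  ct <- colocalization_test(pts, radius = 10, m = 199, seed = 1)
  ab <- ct$per_slide[ct$per_slide$type_a == "A" &
                       ct$per_slide$type_b == "B", ]
  expect_gt(ab$observed, 0)
  expect_lt(ab$p, 0.05)
  expect_equal(ab$p, (ab$b + 1) / (ab$m + 1))
  sc <- ct$score[ct$score$type_a == "A" & ct$score$type_b == "B", ]
  expect_equal(sc$score, 1)  # one slide, significant, positive
  expect_true(all(ct$per_slide$p >= 1 / 200 & ct$per_slide$p <= 1))
  expect_true(all(ct$per_slide$b >= 0 & ct$per_slide$b <= ct$per_slide$m))
  # seed-reproducible
  ct2 <- colocalization_test(pts, radius = 10, m = 199, seed = 1)
  expect_identical(ct$per_slide, ct2$per_slide)
  expect_error(colocalization_test(pts[pts$group == "distal", ],
                                   radius = 10, m = 50), "both contrast")
})

test_that("label images round-trip as text grids", {
  d <- withr::local_tempdir()
  m <- matrix(sample(0:2, 20, TRUE), 4, 5)
  write_label_image(label_image(m, 0.138), file.path(d, "img.txt"))
  back <- read_label_image(file.path(d, "img.txt"), 0.138)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
  expect_equal(attr(back, "pixel_size"), 0.138)
})
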