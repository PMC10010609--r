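test_that("architectures are read with validation and diameter defaults", {
  tab <- data.frame(axis_id = c("P", "L1", "L2"),
                    parent_axis = c(NA, "P", "P"),
                    insertion_position_m = c(0, 0.1, 0.2),
                    length_m = c(0.30, 0.05, 0.04),
                    order = c(0L, 1L, 1L))
  rs <- read_architecture(tab, condition = "CTR")
  expect_s3_class(rs, "root_system")
  expect_equal(nrow(rs$axes), 3)
  expect_equal(rs$axes$diameter[rs$axes$order == 0L], 1.05e-3)
  expect_equal(unique(rs$axes$diameter[rs$axes$order == 1L]), 0.36e-3)
  rs_peg <- read_architecture(tab, condition = "PEG")
  expect_equal(rs_peg$axes$diameter[rs_peg$axes$order == 0L], 1.03e-3)

  # orphan lateral
  bad <- tab; bad$parent_axis[2] <- "missing"
  expect_error(read_architecture(bad), "parent")
  # insertion beyond the parent's length
  bad <- tab; bad$insertion_position_m[3] <- 0.4
  expect_error(read_architecture(bad), "insertion_position")
  # CSV round trip at full precision
  f <- withr::local_tempfile(fileext = ".csv")
  write_architecture(rs, f)
  rs2 <- read_architecture(f)
  expect_equal(rs2$axes$length, rs$axes$length, tolerance = 1e-12)
  expect_equal(rs2$axes$insertion_position, rs$axes$insertion_position,
               tolerance = 1e-12)
})

test_that("reconstruction from cut segments restores lengths and positions", {
  basal <- line_rs(0.05)
  sets <- list(
    list(primary_length = 0.04,
         laterals = data.frame(insertion_position = 0.01, length = 0.03)),
    list(primary_length = 0.08,
         laterals = data.frame(insertion_position = 0.02, length = 0.05)))
  rs <- reconstruct_from_cuts(sets, basal)
  expect_equal(rs$axes$length[rs$axes$order == 0L], 0.17)
  ins <- sort(rs$axes$insertion_position[rs$axes$order == 1L])
  # first (most distal) piece keeps its own tip distance; second is offset
  expect_equal(ins, c(0.01, 0.04 + 0.02))
  expect_error(reconstruct_from_cuts(list(list(laterals = NULL)), basal),
               "primary")
})

test_that("virtual cutting then reconstruction recovers the original", {
  rs <- generate_synthetic_rsa(primary_length = 0.3, lateral_density = 50,
                               seed = 42)
  blades <- c(0.08, 0.13, 0.2)
  vc <- virtual_cut_sets(rs, blades)
  rec <- reconstruct_from_cuts(vc$cut_sets, vc$basal_remainder)
  expect_equal(rec$axes$length[rec$axes$order == 0L],
               rs$axes$length[rs$axes$order == 0L], tolerance = 1e-9)
  expect_equal(sort(rec$axes$insertion_position[rec$axes$order == 1L]),
               sort(rs$axes$insertion_position[rs$axes$order == 1L]),
               tolerance = 1e-9)
  expect_equal(sort(rec$axes$length[rec$axes$order == 1L]),
               sort(rs$axes$length[rs$axes$order == 1L]), tolerance = 1e-9)
})

test_that("discretization uses equal-length REVs and conserves geometry", {
  g <- discretize(line_rs(0.010), 1e-3)
  expect_equal(nrow(g$nodes), 10)
  expect_true(all(abs(g$nodes$length - 1e-3) < 1e-15))

  g2 <- discretize(line_rs(0.0104), 1e-3)
  expect_equal(nrow(g2$nodes), 11)
  expect_equal(unique(round(g2$nodes$length, 10)), round(0.0104 / 11, 10))

  rs <- branched_rs(primary = 0.3, insertions = c(0.07, 0.15, 0.22),
                    lengths = c(0.031, 0.052, 0.013))
  g3 <- discretize(rs, 1e-3)
  expect_equal(sum(g3$nodes$length), sum(rs$axes$length),
               tolerance = 1e-12)
  expect_equal(sum(g3$nodes$surface),
               sum(pi * rs$axes$diameter * rs$axes$length),
               tolerance = 1e-10)
  # distance to tip decreases from base to apex along each axis
  for (ax in unique(g3$nodes$axis_id)) {
    d <- g3$nodes$dist_tip[g3$nodes$axis_id == ax]
    expect_true(all(diff(d) < 0))
  }
  # surfaces consistent with geometry
  expect_equal(g3$nodes$surface,
               pi * g3$nodes$diameter * g3$nodes$length, tolerance = 1e-12)
})

test_that("lateral bases attach to the primary REV containing the insertion", {
  rs <- branched_rs(primary = 0.01, insertions = 0.0035, lengths = 0.002)
  g <- discretize(rs, 1e-3)
  lat_base <- g$nodes[g$nodes$order == 1L, ][1, ]
  parent <- g$nodes[g$nodes$rev_id == lat_base$parent, ]
  expect_equal(parent$order, 0L)
  # insertion 3.5 mm from the tip of a 10 mm axis = REV 7 of 10 (from base)
  expect_true(parent$dist_tip > 0.003 && parent$dist_tip < 0.004)
})

test_that("cutting follows the stretched-tipward lateral convention", {
  mk <- function(p, L) discretize(branched_rs(0.3, p, L), 1e-3)
  # attachment below the blade: whole lateral removed
  g <- cut_at_distance(mk(0.08, 0.12), 0.10)
  expect_equal(sum(g$nodes$order == 1L), 0)
  # blade inside the stretched span: basal 0.05 m kept, cut face flagged
  g <- cut_at_distance(mk(0.15, 0.12), 0.10)
  kept <- g$nodes[g$nodes$order == 1L, ]
  expect_equal(sum(kept$length), 0.05, tolerance = 1e-3)
  distal <- kept[which.min(kept$dist_tip), ]
  expect_true(distal$is_cut_face)
  # short lateral wholly basal of the blade: untouched
  g0 <- mk(0.15, 0.03)
  g <- cut_at_distance(g0, 0.10)
  expect_equal(sum(g$nodes$order == 1L), sum(g0$nodes$order == 1L))
  expect_false(any(g$nodes$is_cut_face[g$nodes$order == 1L]))
  # the new distal primary REV is an open face
  prim <- g$nodes[g$nodes$order == 0L, ]
  expect_true(prim$is_cut_face[which.min(prim$dist_tip)])
  expect_error(cut_at_distance(g0, 0.31), "primary")
})

test_that("cutting is idempotent and total length decreases with the blade", {
  rs <- generate_synthetic_rsa(primary_length = 0.3, lateral_density = 60,
                               seed = 7)
  g <- discretize(rs, 1e-3)
  g1 <- cut_at_distance(g, 0.12)
  g2 <- cut_at_distance(g1, 0.12)
  expect_equal(sum(g2$nodes$length), sum(g1$nodes$length), tolerance = 1e-12)
  expect_equal(nrow(g2$nodes), nrow(g1$nodes))
  lens <- vapply(c(0.05, 0.1, 0.15, 0.2),
                 function(x) sum(cut_at_distance(g, x)$nodes$length),
                 numeric(1))
  expect_true(all(diff(lens) < 0))
})

test_that("the synthetic generator is reproducible and calibrated", {
  a <- generate_synthetic_rsa(seed = 5)
  b <- generate_synthetic_rsa(seed = 5)
  expect_identical(a$axes, b$axes)

  solo <- generate_synthetic_rsa(lateral_density = 0, seed = 1)
  expect_equal(nrow(solo$axes), 1)

  counts <- vapply(1:40, function(s) {
    sum(generate_synthetic_rsa(primary_length = 0.3, lateral_density = 100,
                               seed = s)$axes$order == 1L)
  }, numeric(1))
  lambda <- 100 * (0.3 - 0.02)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))
  # apical unbranched zone respected
  expect_true(all(a$axes$insertion_position[a$axes$order == 1L] >= 0.02))
})

test_that("the default cut schedule mirrors the experimental protocol", {
  cuts <- default_cut_schedule(0.35)
  expect_equal(cuts[1], 0.083)
  expect_true(all(abs(diff(cuts) - 0.043) < 1e-12))
  expect_gte(0.35 - max(cuts), 0.052 - 1e-9)
  expect_equal(length(cuts), 6)
})
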