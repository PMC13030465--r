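test_that("generator produces the requested number of instances", {
  s1 <- generate_tissue(synth_config(64, 64, n_cells = 1, seed = 2,
                                     overexposure_blobs = 0, noise_sigma = 0,
                                     blur_sigma = 0))
  pos <- unique(s1$instance_map[s1$instance_map > 0])
  expect_identical(pos, 1L) # exactly one positive label
  expect_equal(flood_count(s1$instance_map == 1L, 4), 1)

  s50 <- generate_tissue(synth_config(128, 128, n_cells = 50, seed = 42))
  expect_equal(max(s50$instance_map), 50)
  # flood-fill oracle: each label is one connected region and counts agree
  expect_equal(flood_count(s50$instance_map > 0, 4), 50)
})

test_that("generator is deterministic and validates its configuration", {
  cfg <- synth_config(64, 64, n_cells = 9, seed = 5)
  expect_identical(generate_tissue(cfg), generate_tissue(cfg))
  expect_error(synth_config(16, 64), "height")
  expect_error(generate_tissue(synth_config(32, 32, n_cells = 400, seed = 1)),
               "cannot place|degenerate")
})

test_that("saturation comes only from overexposure blobs", {
  s <- generate_tissue(synth_config(64, 64, n_cells = 8, seed = 3,
                                    overexposure_blobs = 0, noise_sigma = 0))
  expect_lt(max(s$image), 1.0)
  sb <- generate_tissue(synth_config(64, 64, n_cells = 8, seed = 3,
                                     overexposure_blobs = 2, noise_sigma = 0))
  expect_equal(max(sb$image), 1.0)
})

test_that("vessel cells are class 2 and larger than the parenchyma median", {
  s <- generate_tissue(synth_config(128, 128, n_cells = 40,
                                    vessel_fraction = 0.1, seed = 9))
  vessel_ids <- unique(s$instance_map[s$class_mask == 2L])
  vessel_ids <- vessel_ids[vessel_ids > 0]
  expect_length(vessel_ids, 4) # round(0.1 * 40)
  areas <- tabulate(s$instance_map[s$instance_map > 0], nbins = 40)
  expect_gt(min(areas[vessel_ids]), stats::median(areas[-vessel_ids]))
})

test_that("derive_targets matches hand enumeration on the 4x4 square", {
  s <- square_sample()
  tg <- derive_targets(s, boundary_width = 1)
  expect_equal(sum(tg$boundary), 12) # perimeter ring of the 4x4 square
  expect_equal(sum(tg$interior), 4)  # central 2x2
  expect_true(all(tg$interior + tg$boundary <= 1)) # disjoint
  # erosion/dilation duality: interior = instance minus boundary
  expect_equal(tg$interior, (s$instance_map > 0) - tg$boundary)
})

test_that("shared edges are boundary on both sides; empty maps give empty targets", {
  tg <- derive_targets(touching_sample(), boundary_width = 1)
  # by pixel enumeration only the two centers (2,2) and (5,2) see a full
  # same-instance neighborhood; the other 16 pixels are boundary
  expect_equal(sum(tg$boundary), 16)
  expect_equal(sum(tg$interior), 2)
  expect_equal(tg$interior[2, 2], 1)
  expect_equal(tg$interior[5, 2], 1)
  # the contact line is boundary for both sides
  expect_true(all(tg$boundary[3:4, ] == 1))

  empty <- derive_targets(matrix(0L, 5, 5), matrix(0L, 5, 5))
  expect_equal(sum(empty$boundary), 0)
  expect_equal(sum(empty$interior), 0)
})

test_that("targets are invariant to instance label permutation", {
  s <- tiny_tissue(seed = 21, n_cells = 8)
  tg1 <- derive_targets(s)
  perm <- rev(seq_len(max(s$instance_map)))
  inst2 <- s$instance_map
  inst2[inst2 > 0] <- perm[inst2[inst2 > 0]]
  tg2 <- derive_targets(inst2, s$class_mask)
  expect_equal(tg1$boundary, tg2$boundary)
  expect_equal(tg1$interior, tg2$interior)
})

test_that("one-hot targets sum to 1 and interiors stay inside annotated tissue", {
  s <- tiny_tissue(seed = 13, n_cells = 10)
  tg <- derive_targets(s)
  expect_true(all(apply(tg$onehot, c(1, 2), sum) == 1))
  expect_true(all(s$class_mask[tg$interior == 1] > 0))
})

test_that("image sample invariants are enforced", {
  img <- array(0.5, c(8, 8, 3))
  cls <- matrix(0L, 8, 8)
  inst <- matrix(0L, 8, 8)
  inst[2, 2] <- 1L
  expect_error(image_sample(img, cls, inst), "positive class")
  inst[2, 2] <- 2L; cls[2, 2] <- 1L
  expect_error(image_sample(img, cls, inst), "consecutive")
})
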