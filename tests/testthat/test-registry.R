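test_that("registry holds exactly 32 landmarks with the documented regional layout", {
  reg <- landmarkRegistry()
  expect_equal(nrow(reg), 32L)
  expect_false(anyDuplicated(reg$name) > 0)
  counts <- table(factor(reg$organ, levels = organNames()))
  expect_equal(as.integer(counts), c(8L, 7L, 7L, 4L, 3L, 3L))
  # lateral face regions are single-sided by construction
  expect_true(all(reg$laterality[reg$organ == "right_face"] == "right"))
  expect_true(all(reg$laterality[reg$organ == "left_face"] == "left"))
  # 10 pairs x 2 + 12 midline = 32
  expect_equal(sum(reg$laterality == "midline"), 12L)
  expect_equal(sum(reg$laterality == "left"), 10L)
  expect_equal(sum(reg$laterality == "right"), 10L)
})

test_that("every lateral landmark has exactly one mirror partner", {
  reg <- landmarkRegistry()
  pairs <- symmetricPairs()
  expect_equal(nrow(pairs), 10L)
  expect_setequal(pairs$abbreviation,
                  c("En", "Ex", "Ps", "Pi", "Al", "Cph", "Ch", "Tra", "Zy", "Go"))
  expect_true(all(c("Endocanthion_left", "Endocanthion_right") %in%
                  c(pairs$left, pairs$right)))
  for (i in seq_len(nrow(pairs))) {
    l <- reg[reg$name == pairs$left[i], ]
    r <- reg[reg$name == pairs$right[i], ]
    expect_equal(l$abbreviation, r$abbreviation)
    expect_equal(l$laterality, "left")
    expect_equal(r$laterality, "right")
  }
  # no midline landmark appears in any pair
  mids <- reg$name[reg$laterality == "midline"]
  expect_length(intersect(mids, c(pairs$left, pairs$right)), 0L)
})

test_that("organSpec partitions the registry and reports per-region output sizes", {
  expect_equal(organSpec("chin")$n_landmarks, 4L)
  expect_equal(organSpec("left_face")$landmark_names,
               c("Tragus_left", "Zygion_left", "Gonion_left"))
  all_names <- unlist(lapply(organNames(), function(o) organSpec(o)$landmark_names))
  expect_equal(sort(all_names), sort(landmarkRegistry()$name))
  expect_equal(length(all_names), 32L)  # no overlap, no omission
  expect_error(organSpec("ears"), "valid organs")
})

test_that("registry JSON export round-trips with stable ordering", {
  path <- withr::local_tempfile(fileext = ".json")
  writeRegistryJSON(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$name, landmarkRegistry()$name)
  expect_equal(back$organ, landmarkRegistry()$organ)
})
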