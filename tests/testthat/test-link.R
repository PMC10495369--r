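test_that("a stationary spot over 50 frames makes one track of length 50", {
  spots <- data.frame(frame = 0:49, x = 20 + rnorm(50, 0, 0.05),
                      y = 30 + rnorm(50, 0, 0.05), amplitude = 100)
  ts <- link_spots(spots, max_disp = 5, max_gap = 2)
  expect_equal(nrow(ts$tracks), 1L)
  expect_equal(ts$tracks$length_frames, 50L)
  expect_false(ts$tracks$merged)
  # empty input stays empty
  ts0 <- link_spots(spots[0, ], 5, 2)
  expect_equal(nrow(ts0$tracks), 0L)
  expect_equal(nrow(filter_tracks(ts0)$tracks), 0L)
})

test_that("gap closing bridges short disappearances but not long ones", {
  spots <- data.frame(frame = c(0:9, 12:19), x = 10, y = 10, amplitude = 1)
  ts <- link_spots(spots, max_disp = 5, max_gap = 2)
  expect_equal(nrow(ts$tracks), 1L)          # 2-frame gap closed
  expect_equal(ts$tracks$length_frames, 20L) # spanned frames incl. the gap
  spots2 <- data.frame(frame = c(0:9, 14:19), x = 10, y = 10, amplitude = 1)
  ts2 <- link_spots(spots2, max_disp = 5, max_gap = 2)
  expect_equal(nrow(ts2$tracks), 2L)         # 4-frame gap not closed
})

test_that("track filter: length 5 removed, 6 kept, merged tracks dropped", {
  mk <- function(n, x) data.frame(frame = seq_len(n) - 1L, x = x, y = 10,
                                  amplitude = 1)
  ts <- link_spots(rbind(mk(5, 10), mk(6, 40)), 5, 2)
  kept <- filter_tracks(ts, min_len = 5)
  expect_equal(nrow(kept$tracks), 1L)
  expect_equal(kept$tracks$length_frames, 6L)
  expect_equal(unname(attr(kept, "exclusions")["short_track"]), 1L)
  # merged-flag track of length 100 is removed
  ts$tracks$merged[1] <- TRUE
  ts$tracks$length_frames[1] <- 100L
  kept2 <- filter_tracks(ts, min_len = 5)
  expect_false(any(kept2$tracks$merged))
})

test_that("two tracks crossing through one spot raise merge/split flags", {
  frames <- 0:10
  a <- data.frame(frame = frames, x = 10 + 2 * frames, y = 10, amplitude = 1)
  b <- data.frame(frame = frames, x = 30 - 2 * frames, y = 10, amplitude = 1)
  spots <- rbind(a[a$frame != 5, ], b[b$frame != 5, ],
                 data.frame(frame = 5, x = 20, y = 10, amplitude = 1))
  ts <- link_spots(spots, max_disp = 5, max_gap = 2)
  expect_true(any(ts$tracks$merged | ts$tracks$split))
})

test_that("RNA-protein linking enforces the 5-frame overlap boundary", {
  rna_spots <- data.frame(frame = 0:19, x = 10, y = 10, amplitude = 50)
  rna <- link_spots(rna_spots, 5, 2)
  prot5 <- link_spots(data.frame(frame = 0:4, x = 10, y = 10, amplitude = 9), 5, 2)
  prot4 <- link_spots(data.frame(frame = 0:3, x = 10, y = 10, amplitude = 9), 5, 2)
  lk5 <- link_rna_protein(rna, list(ch1 = prot5), max_dist = 3, min_overlap = 5)
  expect_equal(lk5$links$ch1_track[1], 1L)      # exactly 5 frames: linked
  expect_equal(lk5$links$overlap_ch1[1], 5L)
  lk4 <- link_rna_protein(rna, list(ch1 = prot4), max_dist = 3, min_overlap = 5)
  expect_true(is.na(lk4$links$ch1_track[1]))    # 4 frames: not linked
  expect_equal(lk4$orphans$protein_track, 1L)
  # no temporal overlap at all: orphan
  prot_late <- link_spots(data.frame(frame = 30:40, x = 10, y = 10,
                                     amplitude = 9), 5, 2)
  lk0 <- link_rna_protein(rna, list(ch1 = prot_late), 3, 5)
  expect_true(is.na(lk0$links$ch1_track[1]))
  expect_equal(nrow(lk0$orphans), 1L)
})

test_that("linking picks the nearest RNA, breaks ties low, fills absent frames with 0", {
  rna_spots <- rbind(data.frame(frame = 0:19, x = 10, y = 10, amplitude = 50),
                     data.frame(frame = 0:19, x = 14, y = 10, amplitude = 50))
  rna <- link_spots(rna_spots, 5, 2)
  prot <- link_spots(data.frame(frame = 0:9, x = 12, y = 10, amplitude = 7), 5, 2)
  lk <- link_rna_protein(rna, list(ch1 = prot), max_dist = 3, min_overlap = 5)
  linked_to <- lk$links$rna_track[!is.na(lk$links$ch1_track)]
  expect_equal(linked_to, 1L)  # equidistant: deterministic tie-break to lower id
  tr <- lk$traces[lk$traces$rna_track == 1L, ]
  expect_equal(nrow(tr), 20L)
  expect_true(all(tr$ch1_signal[tr$frame > 9] == 0))
  expect_true(all(tr$ch1_signal[tr$frame <= 9] == 7))
  # re-running the pairing on the same inputs is reproducible
  lk2 <- link_rna_protein(rna, list(ch1 = prot), max_dist = 3, min_overlap = 5)
  expect_identical(lk$links, lk2$links)
})
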