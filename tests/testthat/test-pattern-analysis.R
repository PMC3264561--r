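test_that("planted clusters are recovered exactly", {
  ## four disjoint groups on a 6x6 grid, staggered onsets
  plants <- list(
    list(cells = c(1, 2), t_on = 2, t_off = 10),
    list(cells = c(6, 12), t_on = 3, t_off = 10),
    list(cells = c(31, 32), t_on = 6, t_off = 10),
    list(cells = c(22, 28), t_on = 7, t_off = 10))
  tr <- planted_trace(6, 6, plants, times = 1:10)
  cl <- detect_clusters(tr, A_threshold = 1, t_gap = 3)
  expect_length(cl, 4L)
  got <- lapply(cl, `[[`, "members")
  for (p in plants)
    expect_true(any(vapply(got, function(g) setequal(g, p$cells), logical(1))))
  onsets <- sort(vapply(cl, `[[`, numeric(1), "onset_time"))
  expect_equal(onsets, c(2, 3, 6, 7))
})

test_that("a second lobe joining an active cluster soon after is one organ", {
  plants <- list(
    list(cells = 15, t_on = 2, t_off = 10),
    list(cells = 16, t_on = 3, t_off = 10))   # adjacent, 1 sample later
  tr <- planted_trace(6, 6, plants, times = 1:10)
  cl <- detect_clusters(tr, A_threshold = 1, t_gap = 10)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$onset_time, 2)
  expect_setequal(cl[[1]]$members, c(15, 16))
})

test_that("a maximum re-emerging at a silent site counts as a new organ after t_gap", {
  plants <- list(
    list(cells = c(8, 9), t_on = 1, t_off = 3),
    list(cells = c(8, 9), t_on = 10, t_off = 12))
  tr <- planted_trace(6, 6, plants, times = 1:12)
  expect_length(detect_clusters(tr, 1, t_gap = 4), 2L)
  expect_length(detect_clusters(tr, 1, t_gap = 8), 1L)    # within the gap: same organ
})

test_that("fusion is merged only when it persists to the trace end", {
  ## two groups that grow together and stay together
  plants <- list(
    list(cells = c(1, 2), t_on = 1, t_off = 12),
    list(cells = c(4, 5), t_on = 2, t_off = 12),
    list(cells = 3, t_on = 6, t_off = 12))     # the bridge (cells 1..6 = row 1)
  tr <- planted_trace(6, 6, plants, times = 1:12)
  cl <- detect_clusters(tr, 1, t_gap = 2)
  expect_length(cl, 2L)                        # the bridge joins the older one
  merged <- merge_fused(cl, tr, 1)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$onset_time, 1)
  expect_setequal(merged[[1]]$members, 1:5)

  ## transient bridge that re-separates: stays two organs
  plants2 <- list(
    list(cells = c(1, 2), t_on = 1, t_off = 12),
    list(cells = c(4, 5), t_on = 2, t_off = 12),
    list(cells = 3, t_on = 5, t_off = 6))
  tr2 <- planted_trace(6, 6, plants2, times = 1:12)
  cl2 <- detect_clusters(tr2, 1, t_gap = 2)
  merged2 <- merge_fused(cl2, tr2, 1)
  expect_length(merged2, 2L)
  sizes <- sort(vapply(merged2, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(2L, 3L))               # bridge absorbed by the older

  ## clusters that never touch are untouched
  expect_length(merge_fused(detect_clusters(
    planted_trace(6, 6, plants[1:2], 1:12), 1, 2),
    planted_trace(6, 6, plants[1:2], 1:12), 1), 2L)
})

test_that("organ classes follow the whorl circle and the stage-2 onset rule", {
  ## 11x11 grid; center cell vs a corner-adjacent rim cell
  rim <- 1:3            # row-1 corner cells: radial fraction ~ 1
  ctr <- c(61)          # center of the 11x11 grid
  plants <- list(
    list(cells = rim, t_on = 2, t_off = 20),          # early outer -> sepal
    list(cells = 111:113, t_on = 12, t_off = 20),     # late outer -> petal
    list(cells = ctr, t_on = 2, t_off = 20))          # inner -> reproductive
  tr <- planted_trace(11, 11, plants, times = 1:20)
  cl <- detect_clusters(tr, 1, t_gap = 3)
  cl <- classify_organs(cl, tr, whorl_radius_fraction = 0.5, stage2_time = 10)
  cls <- setNames(vapply(cl, `[[`, character(1), "organ_class"),
                  vapply(cl, function(x) paste(x$members, collapse = ","), character(1)))
  expect_equal(unname(cls[paste(rim, collapse = ",")]), "sepal")
  expect_equal(unname(cls[paste(111:113, collapse = ",")]), "petal")
  expect_equal(unname(cls[paste(ctr, collapse = ",")]), "reproductive")
  rep <- organ_report(cl, run_seed = 1L)
  expect_equal(unname(rep$counts), c(1, 1, 1))
  ## the three classes are exhaustive and exclusive
  expect_true(all(vapply(cl, `[[`, character(1), "organ_class") %in%
                  c("sepal", "petal", "reproductive")))
})

test_that("cluster detection is invariant under rigid transforms of coordinates", {
  plants <- list(list(cells = c(1, 2), t_on = 1, t_off = 5),
                 list(cells = 36, t_on = 2, t_off = 5))
  tr <- planted_trace(6, 6, plants, times = 1:5)
  tr2 <- tr
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (i in seq_along(tr2$snapshots))
    tr2$snapshots[[i]]$centroid <- tr2$snapshots[[i]]$centroid %*% t(R) + 5
  c1 <- detect_clusters(tr, 1, 2); c2 <- detect_clusters(tr2, 1, 2)
  expect_equal(lapply(c1, `[[`, "members"), lapply(c2, `[[`, "members"))
})

test_that("batch summaries compute pattern frequencies and class variation", {
  rep1 <- structure(list(counts = c(sepal = 4, petal = 4, reproductive = 5),
                         pattern = c(4, 4, 5), run_seed = 1L),
                    class = "organ_report")
  b <- summarize_batch(rep(list(rep1), 50))
  expect_equal(unname(b$pattern_frequency["4-4-5"]), 50L)
  expect_equal(b$per_class$cv_percent, rep(0, 3))

  rep2 <- structure(list(counts = c(sepal = 4, petal = 5, reproductive = 5),
                         pattern = c(4, 5, 5), run_seed = 2L),
                    class = "organ_report")
  b2 <- summarize_batch(list(rep1, rep2))
  pet <- b2$per_class[b2$per_class$class == "petal", ]
  expect_equal(pet$mean, 4.5)
  expect_equal(pet$sd, sd(c(4, 5)), tolerance = 1e-12)
  expect_equal(pet$cv_percent, 100 * sd(c(4, 5)) / 4.5, tolerance = 1e-12)

  b1 <- summarize_batch(list(rep1))
  expect_false(b1$sd_defined)
  expect_equal(b1$per_class$sd, rep(0, 3))
  expect_error(summarize_batch(list()))
})
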