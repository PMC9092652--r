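test_that("long-format CSV loads with column mapping and drops incomplete rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Mouse,Group,Day,Weight",
               "m1,A,0,1.0", "m1,A,7,2.5", "m2,B,0,0.5", "m2,B,7,3.0",
               "m2,B,14,NA"),
             path)
  ds <- load_long_csv(path, c(subject = "Mouse", group = "Group",
                              time = "Day", response = "Weight"))
  expect_s3_class(ds, "long_dataset")
  expect_equal(nrow(ds), 4)
  expect_equal(length(unique(ds$subject)), 2)
  expect_equal(attr(ds, "n_dropped"), 1)
  unlink(path)
})

test_that("CSV loader rejects schema, cardinality and nesting violations", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject,group,time,response", "s1,A,0,1", "s1,A,1,2"), path)
  expect_error(load_long_csv(path, c(subject = "subject", group = "group",
                                     time = "day", response = "response")),
               "not in file")
  writeLines(c("subject,group,time,response",
               "s1,A,0,1", "s1,A,1,2", "s2,B,0,1", "s2,B,1,2",
               "s3,C,0,1", "s3,C,1,2"), path)
  expect_error(load_long_csv(path), "2 levels")
  writeLines(c("subject,cluster,group,time,response",
               "M1,d1,A,0,1", "M1,d2,A,1,2", "M2,d2,B,0,1", "M2,d2,B,1,2"),
             path)
  expect_error(load_long_csv(path), "nesting violation")
  unlink(path)
})

test_that("write/load round trip is the identity on records", {
  ds <- make_demo_dataset(seed = 4)
  path <- tempfile(fileext = ".csv")
  write_long_csv(ds, path)
  back <- load_long_csv(path)
  expect_equal(nrow(back), nrow(ds))
  for (col in c("subject", "cluster", "time", "response")) {
    expect_equal(back[[col]], ds[[col]])
  }
  expect_equal(as.character(back$group), as.character(ds$group))
  unlink(path)
})

test_that("design builder yields the published cell counts", {
  expect_equal(nrow(build_design(blanton_grid())), 480)
  expect_equal(nrow(build_design(simulation_grid())), 480)
  g1 <- design_grid(groups = "only", donors_per_group = 1, mice_per_donor = 1,
                    timepoints = 0)
  expect_equal(nrow(build_design(g1)), 1)
  expect_error(design_grid(timepoints = numeric(0)), "non-empty")
  expect_error(design_grid(timepoints = c(0, 0, 1)), "strictly increasing")
})

test_that("design cell count matches the closed-form product on random grids", {
  set.seed(11)
  for (rep in 1:20) {
    ng <- sample(1:2, 1)
    dpg <- sample(1:4, ng, replace = TRUE)
    mpd <- sample(1:4, 1)
    nt <- sample(2:5, 1)
    grid <- design_grid(groups = letters[seq_len(ng)], donors_per_group = dpg,
                        mice_per_donor = mpd,
                        timepoints = sort(sample(0:30, nt)))
    ds <- build_design(grid)
    expect_equal(nrow(ds), sum(dpg) * mpd * nt)
    expect_equal(nrow(ds), n_cells(grid))
    # deterministic ordering: ascending time within subject
    expect_true(all(tapply(ds$time, ds$subject, function(x) all(diff(x) > 0))))
  }
})

test_that("MCAR thinning removes exactly n_missing records, reproducibly", {
  ds <- build_design(blanton_grid())
  ds$response <- seq_len(nrow(ds))
  ds <- long_dataset(as.data.frame(ds), grid = blanton_grid())
  thinned <- apply_missingness(ds, 43, seed = 1)
  expect_equal(nrow(thinned), 437)
  # determinism
  thinned2 <- apply_missingness(ds, 43, seed = 1)
  expect_identical(attr(thinned, "removed"), attr(thinned2, "removed"))
  # kept + removed reconstructs the input
  removed <- attr(thinned, "removed")
  expect_equal(length(removed), 43)
  expect_setequal(c(thinned$response, ds$response[removed]), ds$response)
  # no subject is emptied
  expect_equal(length(unique(thinned$subject)), length(unique(ds$subject)))
  # zero removal is the identity
  zero <- apply_missingness(ds, 0, seed = 9)
  expect_equal(zero$response, ds$response)
  expect_equal(zero$subject, ds$subject)
  expect_length(attr(zero, "removed"), 0)
  expect_error(apply_missingness(ds, 480, seed = 1), "n_missing")
})

test_that("infeasible missingness (would empty a subject) errors", {
  ds <- long_dataset(data.frame(subject = c("a", "a", "b"),
                                group = c("A", "A", "B"),
                                time = c(0, 1, 0),
                                response = 1:3))
  expect_error(apply_missingness(ds, 2, seed = 1), "infeasible")
})

test_that("validation report counts missing design cells and flags singleton subjects", {
  demo <- make_demo_dataset(seed = 2)
  rep_demo <- validate_dataset(demo)
  expect_equal(rep_demo$n_missing_cells, 43)
  expect_equal(rep_demo$n_records, 437)
  expect_equal(rep_demo$n_subjects, 40)
  expect_equal(rep_demo$n_clusters, 8)

  full <- build_design(blanton_grid())
  expect_equal(validate_dataset(full)$n_missing_cells, 0)

  single <- long_dataset(data.frame(
    subject = c("a", "a", "b"), group = c("A", "A", "B"),
    time = c(0, 1, 3), response = c(1, 2, 3)))
  rep_single <- validate_dataset(single)
  expect_true(any(grepl("single time point", rep_single$issues$message)))
  expect_true(any(rep_single$issues$severity == "warning"))
})

test_that("dataset constructor enforces nesting and uniqueness invariants", {
  expect_error(long_dataset(data.frame(
    subject = c("M1", "M1"), cluster = c("d1", "d2"),
    group = "A", time = c(0, 1), response = 1:2)), "nesting violation")
  expect_error(long_dataset(data.frame(
    subject = "s", group = "A", time = c(0, 0), response = 1:2)),
    "duplicate")
  expect_error(long_dataset(data.frame(
    subject = c("s", "s"), group = "A", time = c(0, Inf), response = 1:2)),
    "non-finite")
})
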