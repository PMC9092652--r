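# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic small-integer seed derived from a root seed and a label,
# used to give each simulation cell / replicate its own stream.
derive_seed <- function(seed, label) {
  m <- 2147483563
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  as.integer((h * 48271) %% m) + 1L
}

#' Construct a longitudinal dataset
#'
#' A `long_dataset` is a long-format data frame with one row per observation
#' and columns `subject`, `group`, `time`, `response` plus an optional
#' `cluster` column holding a higher-level grouping factor (e.g. the donor a
#' mouse received its transplant from). Nesting is strict: every subject
#' belongs to exactly one group and, when present, exactly one cluster.
#'
#' @param df data frame with the columns above (`cluster` optional,
#'   `response` may contain `NA` for design skeletons).
#' @param grid optional [design_grid()] the data were laid out on; retained so
#'   [validate_dataset()] can count missing design cells.
#' @return A data frame of class `long_dataset`.
#' @export
long_dataset <- function(df, grid = NULL) {
  req <- c("subject", "group", "time", "response")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$subject <- as.character(df$subject)
  if ("cluster" %in% names(df)) df$cluster <- as.character(df$cluster)
  df$time <- as.numeric(df$time)
  df$response <- as.numeric(df$response)
  if (!is.factor(df$group)) df$group <- factor(df$group)
  df$group <- droplevels(df$group)
  if (nlevels(df$group) > 2) {
    stop("group must have at most 2 levels, found ", nlevels(df$group))
  }
  if (any(!is.finite(df$time))) stop("non-finite time values")
  if (anyDuplicated(paste(df$subject, df$time, sep = "\r"))) {
    stop("duplicate (subject, time) pairs")
  }
  # design skeletons (all responses unset) may carry a single timepoint;
  # observed datasets need at least two for a trajectory
  if (length(unique(df$time)) < 2 && !all(is.na(df$response))) {
    stop("need at least 2 distinct time values")
  }
  sub_group <- tapply(as.character(df$group), df$subject,
                      function(g) length(unique(g)))
  if (any(sub_group > 1)) {
    stop("nesting violation: subject(s) mapped to multiple groups: ",
         paste(names(sub_group)[sub_group > 1], collapse = ", "))
  }
  if ("cluster" %in% names(df)) {
    sub_cl <- tapply(df$cluster, df$subject, function(x) length(unique(x)))
    if (any(sub_cl > 1)) {
      stop("nesting violation: subject(s) mapped to multiple clusters: ",
           paste(names(sub_cl)[sub_cl > 1], collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("long_dataset", "data.frame"), grid = grid)
}

#' @export
print.long_dataset <- function(x, ...) {
  cat(sprintf("<long_dataset> %d records, %d subjects, %d clusters, %d timepoints\n",
              nrow(x), length(unique(x$subject)),
              if ("cluster" %in% names(x)) length(unique(x$cluster)) else 0L,
              length(unique(x$time))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Design grid for a nested longitudinal study
#'
#' Describes a fully crossed layout: for each group, a number of donors
#' (clusters), a common number of mice (subjects) per donor, and a shared set
#' of measurement days. The default values reproduce the transplant-study
#' layout analysed throughout the package: 3 healthy and 5 undernourished
#' donors, 5 mice per donor, 12 measurement days between 0 and 32.
#'
#' @param groups character vector of group labels (first label is the
#'   reference level).
#' @param donors_per_group integer count of donors per group; recycled to
#'   `length(groups)`, so unequal group sizes are allowed.
#' @param mice_per_donor integer count of subjects nested in each donor.
#' @param timepoints strictly increasing numeric vector of days.
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(groups = c("healthy", "undernourished"),
                        donors_per_group = c(3L, 5L),
                        mice_per_donor = 5L,
                        timepoints = blanton_timepoints()) {
  if (length(groups) < 1) stop("need at least one group")
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  donors_per_group <- rep_len(as.integer(donors_per_group), length(groups))
  if (any(donors_per_group < 1) || mice_per_donor < 1) {
    stop("counts must be >= 1")
  }
  structure(list(groups = as.character(groups),
                 donors_per_group = donors_per_group,
                 mice_per_donor = as.integer(mice_per_donor),
                 timepoints = as.numeric(timepoints)),
            class = "design_grid")
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("<design_grid> %s donors x %d mice x %d timepoints = %d cells\n",
              paste(x$donors_per_group, collapse = "+"), x$mice_per_donor,
              length(x$timepoints), n_cells(x)))
  invisible(x)
}

#' Number of design cells in a grid
#' @param grid a [design_grid()].
#' @return integer cell count `sum(donors_per_group) * mice_per_donor * n_times`.
#' @export
n_cells <- function(grid) {
  sum(grid$donors_per_group) * grid$mice_per_donor * length(grid$timepoints)
}

#' Measurement days of the re-analysed transplant study
#'
#' The 12 days on which percent weight change was recorded.
#' @return numeric vector of length 12.
#' @export
blanton_timepoints <- function() c(0, 1, 3, 4, 7, 11, 14, 18, 21, 25, 28, 32)

#' Blanton-like nested grid (3 + 5 donors)
#' @return a [design_grid()] with 3 healthy + 5 undernourished donors,
#'   5 mice each, 12 days (480 cells).
#' @export
blanton_grid <- function() design_grid()

#' Balanced simulation grid (4 + 4 donors)
#'
#' The balanced layout used by the simulation study: four donors per group
#' with five mice per donor over the 12 standard days (480 cells).
#' @return a [design_grid()].
#' @export
simulation_grid <- function() {
  design_grid(donors_per_group = c(4L, 4L))
}

#' Expand a design grid into a response-free dataset skeleton
#'
#' One record per (group, donor, mouse, time) cell, in deterministic
#' ascending order, with `response = NA`. Donor labels are `<G><d>` and
#' subject labels `<G><d>.m<m>` where `<G>` is the group's first letter
#' (upper-cased, disambiguated if groups share an initial).
#'
#' @param grid a [design_grid()].
#' @return a [long_dataset()] with `NA` responses and the grid attached.
#' @export
build_design <- function(grid) {
  stopifnot(inherits(grid, "design_grid"))
  initials <- toupper(substr(grid$groups, 1, 1))
  if (anyDuplicated(initials)) initials <- make.unique(initials, sep = "")
  rows <- vector("list", length(grid$groups))
  for (gi in seq_along(grid$groups)) {
    nd <- grid$donors_per_group[gi]
    donors <- paste0(initials[gi], seq_len(nd))
    df <- expand.grid(time = grid$timepoints,
                      mouse = seq_len(grid$mice_per_donor),
                      donor = donors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[gi]] <- data.frame(
      subject = paste0(df$donor, ".m", df$mouse),
      cluster = df$donor,
      group = grid$groups[gi],
      time = df$time,
      response = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$group, grid$groups), out$cluster,
                   out$subject, out$time), , drop = FALSE]
  out$group <- factor(out$group, levels = grid$groups)
  long_dataset(out, grid = grid)
}

#' Remove records completely at random
#'
#' Deletes exactly `n_missing` records chosen uniformly at random (MCAR),
#' reproducibly for a fixed seed. Draws that would leave some subject with no
#' records are rejected and redrawn within the same seed stream; if no
#' feasible draw exists an error is raised.
#'
#' @param ds a [long_dataset()].
#' @param n_missing number of records to drop, `0 <= n_missing < nrow(ds)`.
#' @param seed integer seed.
#' @return the thinned `long_dataset`; the indices of removed rows (relative
#'   to `ds`) are attached as attribute `"removed"`.
#' @export
apply_missingness <- function(ds, n_missing, seed) {
  stopifnot(inherits(ds, "long_dataset"))
  n <- nrow(ds)
  if (n_missing < 0 || n_missing >= n) stop("need 0 <= n_missing < n_records")
  if (n_missing == 0) {
    attr(ds, "removed") <- integer(0)
    return(ds)
  }
  n_subj <- length(unique(ds$subject))
  if (n_missing > n - n_subj) {
    stop("infeasible: removing ", n_missing,
         " records must empty at least one subject")
  }
  removed <- with_seed(seed, {
    idx <- NULL
    for (attempt in 1:1000) {
      cand <- sample.int(n, n_missing)
      if (length(unique(ds$subject[-cand])) == n_subj) {
        idx <- cand
        break
      }
    }
    if (is.null(idx)) {
      stop("could not draw a feasible missingness pattern in 1000 attempts")
    }
    idx
  })
  out <- ds[-removed, , drop = FALSE]
  out <- long_dataset(as.data.frame(out), grid = attr(ds, "grid"))
  attr(out, "removed") <- sort(removed)
  out
}

#' Read a long-format CSV into a dataset
#'
#' @param path CSV file path (comma-separated, header row, `NA` or empty
#'   fields as missing).
#' @param column_map named character vector mapping roles to column names,
#'   e.g. `c(subject = "Mouse", cluster = "Donor", group = "Group",
#'   time = "Day", response = "WeightChange")`. Roles `subject`, `group`,
#'   `time`, `response` are required; `cluster` is optional.
#' @return a [long_dataset()]; rows with missing response or time are dropped
#'   and their count attached as attribute `"n_dropped"`.
#' @export
load_long_csv <- function(path,
                          column_map = c(subject = "subject",
                                         cluster = "cluster",
                                         group = "group",
                                         time = "time",
                                         response = "response")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  required <- c("subject", "group", "time", "response")
  if (!all(required %in% names(column_map))) {
    stop("column_map must name roles: ",
         paste(setdiff(required, names(column_map)), collapse = ", "))
  }
  roles <- intersect(c("subject", "cluster", "group", "time", "response"),
                     names(column_map))
  absent <- column_map[roles][!column_map[roles] %in% names(raw)]
  # an optional cluster column may simply be absent from the file
  if ("cluster" %in% names(absent)) {
    roles <- setdiff(roles, "cluster")
    absent <- absent[names(absent) != "cluster"]
  }
  if (length(absent) > 0) {
    stop("column(s) not in file: ", paste(absent, collapse = ", "))
  }
  df <- raw[, unname(column_map[roles]), drop = FALSE]
  names(df) <- roles
  keep <- !is.na(df$response) & !is.na(df$time)
  n_dropped <- sum(!keep)
  ds <- long_dataset(df[keep, , drop = FALSE])
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Write a dataset as long-format CSV
#' @param ds a [long_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate a dataset and summarize its completeness
#'
#' Produces record/subject/cluster counts, the number of missing design cells
#' when a grid is available, and a list of data issues such as subjects
#' observed at a single time point (whose individual slope is then
#' unidentifiable). Never modifies the data.
#'
#' @param ds a [long_dataset()].
#' @param grid optional [design_grid()]; defaults to the grid attached to
#'   `ds`, if any.
#' @return an object of class `validation_report` with fields `n_records`,
#'   `n_subjects`, `n_clusters`, `n_missing_cells` and `issues` (data frame
#'   with `severity`, `message`).
#' @export
validate_dataset <- function(ds, grid = NULL) {
  stopifnot(inherits(ds, "long_dataset"))
  if (is.null(grid)) grid <- attr(ds, "grid")
  issues <- list()
  add_issue <- function(severity, message) {
    issues[[length(issues) + 1]] <<- data.frame(severity = severity,
                                                message = message)
  }
  tab <- table(ds$subject)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    add_issue("warning", paste0("subject(s) with a single time point (slope ",
                                "unidentifiable): ",
                                paste(singletons, collapse = ", ")))
  }
  if (any(!is.na(ds$response) & !is.finite(ds$response))) {
    add_issue("error", "non-finite response values")
  }
  if (nlevels(ds$group) < 2) {
    add_issue("warning", "only one group level present; group effects are inestimable")
  }
  n_missing_cells <- NA_integer_
  if (!is.null(grid)) {
    n_missing_cells <- n_cells(grid) - nrow(ds)
    if (n_missing_cells < 0) {
      add_issue("error", "more records than design cells in declared grid")
    }
  }
  structure(list(
    n_records = nrow(ds),
    n_subjects = length(unique(ds$subject)),
    n_clusters = if ("cluster" %in% names(ds)) length(unique(ds$cluster)) else 0L,
    n_missing_cells = n_missing_cells,
    issues = if (length(issues) > 0) do.call(rbind, issues)
             else data.frame(severity = character(), message = character())
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> %d records | %d subjects | %d ",
                     "clusters | missing cells: %s\n"),
              x$n_records, x$n_subjects, x$n_clusters,
              ifelse(is.na(x$n_missing_cells), "n/a", x$n_missing_cells)))
  if (nrow(x$issues) == 0) cat("no issues\n") else {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("[%s] %s\n", x$issues$severity[i], x$issues$message[i]))
    }
  }
  invisible(x)
}
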