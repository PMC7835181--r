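#' Read and write regional TAC tables
#'
#' TAC tables are UTF-8 delimited text (comma or tab, auto-detected on read)
#' with a header row and columns `frame_start_s`, `frame_end_s` followed by
#' one column per region. `write_tac_table()` writes at full precision so
#' that `read_tac_table(write_tac_table(x))` round-trips exactly.
#'
#' @param path File path.
#' @param x A data frame with columns `frame_start_s`, `frame_end_s` and one
#'   numeric column per region, or a named list of [tac()]s sharing one
#'   schedule.
#' @param delim Field delimiter for writing (default comma).
#' @return `read_tac_table()` returns a tibble with the schedule columns and
#'   one column per region; the schedule is validated (monotone,
#'   non-overlapping, positive durations — gaps allowed).
#' @export
read_tac_table <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- suppressWarnings(readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed TAC table '", path, "': ",
      paste0("line ", probs$row + 1L, ": ", probs$expected,
        " but got ", probs$actual,
        collapse = "; "
      )
    ))
  }
  if (!all(c("frame_start_s", "frame_end_s") %in% names(tbl))) {
    abort("TAC table must have frame_start_s and frame_end_s columns")
  }
  # validates ordering/overlap/durations; gaps are fine
  as_schedule(tibble::tibble(
    frame_start = tbl$frame_start_s,
    frame_end = tbl$frame_end_s
  ))
  if (!all(vapply(tbl, is.numeric, logical(1)))) {
    abort("all TAC table columns must be numeric")
  }
  tbl
}

#' @rdname read_tac_table
#' @export
write_tac_table <- function(x, path, delim = ",") {
  if (!is.data.frame(x)) {
    x <- tac_table(x)
  }
  if (!all(c("frame_start_s", "frame_end_s") %in% names(x))) {
    abort("x must have frame_start_s and frame_end_s columns")
  }
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Convert between TAC tables and tac objects
#'
#' `tac_table()` binds a named list of [tac()]s sharing a schedule into the
#' wide table layout; `tacs_from_table()` splits a wide table back into a
#' named list of [tac()]s.
#'
#' @param tacs Named list of [tac()]s with identical schedules.
#' @param tbl A TAC table as returned by [read_tac_table()].
#' @param decay_corrected Flag applied to the extracted curves.
#' @return A tibble (respectively a named list of [tac()]s).
#' @export
tac_table <- function(tacs) {
  stopifnot(is.list(tacs), length(tacs) > 0)
  if (is.null(names(tacs)) || any(!nzchar(names(tacs)))) {
    abort("tacs must be a named list")
  }
  ref <- as_schedule(tacs[[1]])
  for (tt in tacs[-1]) {
    s <- as_schedule(tt)
    if (nrow(s) != nrow(ref) || any(abs(s$frame_start - ref$frame_start) > 1e-9)) {
      abort("all TACs must share one frame schedule")
    }
  }
  out <- tibble::tibble(
    frame_start_s = ref$frame_start,
    frame_end_s = ref$frame_end
  )
  for (nm in names(tacs)) out[[nm]] <- tacs[[nm]]$activity
  out
}

#' @rdname tac_table
#' @export
tacs_from_table <- function(tbl, decay_corrected = TRUE) {
  sched <- frame_schedule(tbl$frame_start_s, tbl$frame_end_s)
  regions <- setdiff(names(tbl), c("frame_start_s", "frame_end_s"))
  setNames(
    lapply(regions, function(r) {
      tac(sched, tbl[[r]], label = r, decay_corrected = decay_corrected)
    }),
    regions
  )
}
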