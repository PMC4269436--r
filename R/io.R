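#' Describe the layout of a game-result file
#'
#' Game files arrive in many delimited dialects; a dialect maps the five
#' required roles (round, the two teams, the two scores) onto column names
#' or positions so any layout can be read without editing the file.
#'
#' @param delimiter Field delimiter; default `","`.
#' @param round,team_a,score_a,team_b,score_b Column names (when
#'   `header = TRUE`) or 1-based positions (when `header = FALSE`) carrying
#'   each role; all five must be distinct.
#' @param header Whether the file's first line names its columns.
#' @param encoding Text encoding; default `"UTF-8"`.
#' @return A `game_dialect` object.
#' @export
game_dialect <- function(delimiter = ",", round = "round",
                         team_a = "team_a", score_a = "score_a",
                         team_b = "team_b", score_b = "score_b",
                         header = TRUE, encoding = "UTF-8") {
  cols <- list(round = round, team_a = team_a, score_a = score_a,
               team_b = team_b, score_b = score_b)
  if (anyDuplicated(unlist(cols))) {
    rlang::abort("all five roles must map to distinct columns")
  }
  structure(list(delimiter = delimiter, cols = cols, header = header,
                 encoding = encoding),
            class = "game_dialect")
}

#' Read a delimited game-result file
#'
#' @param path Path to a delimited text file.
#' @param dialect A [game_dialect()]; default the package's canonical
#'   comma-separated layout with a `round,team_a,score_a,team_b,score_b`
#'   header.
#' @return A validated `game_table`. Malformed rows abort with the
#'   offending line number and field; team IDs are kept verbatim.
#' @export
read_games <- function(path, dialect = game_dialect()) {
  stopifnot(inherits(dialect, "game_dialect"))
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- readr::read_delim(
    path, delim = dialect$delimiter,
    col_names = dialect$header,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = dialect$encoding),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  get_col <- function(role) {
    key <- dialect$cols[[role]]
    if (is.numeric(key)) {
      if (key > ncol(raw)) {
        rlang::abort(sprintf("dialect maps %s to column %d but the file has %d columns",
                             role, key, ncol(raw)))
      }
      raw[[key]]
    } else {
      if (!key %in% names(raw)) {
        rlang::abort(sprintf("dialect maps %s to column '%s', absent from the header",
                             role, key))
      }
      raw[[key]]
    }
  }
  tbl <- tibble::tibble(
    round = get_col("round"), team_a = get_col("team_a"),
    score_a = get_col("score_a"), team_b = get_col("team_b"),
    score_b = get_col("score_b")
  )
  line0 <- if (isTRUE(dialect$header)) 1L else 0L
  for (fld in c("round", "score_a", "score_b")) {
    v <- suppressWarnings(as.numeric(tbl[[fld]]))
    bad <- which(is.na(v) & !is.na(tbl[[fld]]) | is.na(tbl[[fld]]))
    if (length(bad) > 0) {
      rlang::abort(sprintf("line %d: field %s ('%s') is not a number",
                           bad[1] + line0, fld, tbl[[fld]][bad[1]]))
    }
    if (fld != "round" && any(v < 0)) {
      bad <- which(v < 0)[1]
      rlang::abort(sprintf("line %d: field %s is negative (%s)",
                           bad + line0, fld, tbl[[fld]][bad]))
    }
    tbl[[fld]] <- v
  }
  bad <- which(tbl$round < 1 | tbl$round != floor(tbl$round))
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d: round must be a positive integer (%s)",
                         bad[1] + line0, tbl$round[bad[1]]))
  }
  bad <- which(tbl$team_a == tbl$team_b)
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d: team_a equals team_b ('%s')",
                         bad[1] + line0, tbl$team_a[bad[1]]))
  }
  as_game_table(tbl)
}

#' Write a game table to a delimited file
#'
#' @param games A game table.
#' @param path Output path.
#' @param dialect A [game_dialect()] (named-column dialects only).
#' @return `path`, invisibly.
#' @export
write_games <- function(games, path, dialect = game_dialect()) {
  games <- as_game_table(games)
  out <- games[, c("round", "team_a", "score_a", "team_b", "score_b")]
  names(out) <- vapply(names(out), function(role) {
    key <- dialect$cols[[role]]
    if (is.numeric(key)) rlang::abort("write_games needs a named-column dialect")
    key
  }, character(1))
  readr::write_delim(out, path, delim = dialect$delimiter,
                     col_names = dialect$header)
  invisible(path)
}

#' Write a rating table as CSV or JSON
#'
#' Floats are written at 12 significant digits so downstream comparisons
#' are reproducible across readers.
#'
#' @param ratings A tibble (e.g. from [rate_teams()] or `tidy(walkrank(...))`).
#' @param path Output path, or `""` for standard output.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path = "", format = c("csv", "json")) {
  format <- match.arg(format)
  num <- vapply(ratings, is.double, logical(1))
  ratings[num] <- lapply(ratings[num], function(x) signif(x, 12))
  if (format == "csv") {
    if (identical(path, "")) {
      utils::write.csv(ratings, stdout(), row.names = FALSE, quote = FALSE)
    } else {
      utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
    }
  } else {
    rlang::check_installed("jsonlite")
    txt <- jsonlite::toJSON(ratings, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE, pretty = TRUE, na = "null")
    if (identical(path, "")) cat(txt, "\n") else writeLines(txt, path)
  }
  invisible(path)
}
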