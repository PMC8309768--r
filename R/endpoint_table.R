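#' Endpoint tables
#'
#' An endpoint table is a data frame keyed by `site`, `tank_id` and (at fish
#' level) `fish_id`, with one column per endpoint. Units are carried in the
#' column names as suffixes (`_mm`, `_mm_s`, `_s`, `_mm2`, `_pct`, `_ratio`),
#' so a written table is self-describing and round-trips losslessly.
#'
#' @param df Data frame with key columns and numeric endpoint columns.
#' @param level `"fish"` or `"tank"`.
#' @return `df` with class `endpoint_table` prepended.
#' @export
endpoint_table <- function(df, level = c("fish", "tank")) {
  level <- match.arg(level)
  keys <- c("site", "tank_id", if (level == "fish") "fish_id")
  missing_keys <- setdiff(keys, names(df))
  if (length(missing_keys)) {
    stop("endpoint_table: missing key column(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("endpoint_table: duplicate keys", call. = FALSE)
  }
  structure(df, class = c("endpoint_table", class(df)),
            level = level)
}

endpoint_columns <- function(table) {
  setdiff(names(table), c("site", "tank_id", "fish_id", "n_per_site"))
}

#' Collapse fish-level endpoints to tank means
#'
#' Tank means are the independent statistical unit of the between-site tests:
#' each endpoint is averaged over the fish of a tank (plain arithmetic mean),
#' and a column with the number of tanks per site is appended.
#'
#' @param per_fish A fish-level `endpoint_table`.
#' @return A tank-level `endpoint_table`, one row per tank.
#' @examples
#' tab <- endpoint_table(data.frame(
#'   site = "site1", tank_id = "t1", fish_id = as.character(1:6),
#'   swim_speed_mm_s = 1:6), level = "fish")
#' collapse_to_tank_means(tab)$swim_speed_mm_s  # 3.5
#' @export
collapse_to_tank_means <- function(per_fish) {
  stopifnot(inherits(per_fish, "endpoint_table"))
  if (identical(attr(per_fish, "level"), "tank")) {
    stop("collapse_to_tank_means: table is already tank-level", call. = FALSE)
  }
  cols <- endpoint_columns(per_fish)
  if (!all(vapply(per_fish[cols], is.numeric, logical(1)))) {
    stop("collapse_to_tank_means: non-numeric endpoint column", call. = FALSE)
  }
  split_key <- interaction(per_fish$site, per_fish$tank_id, drop = TRUE,
                           lex.order = TRUE)
  pieces <- split(per_fish, split_key)
  rows <- lapply(pieces, function(p) {
    means <- lapply(p[cols], mean)
    cbind(data.frame(site = p$site[1L], tank_id = p$tank_id[1L],
                     stringsAsFactors = FALSE),
          as.data.frame(means))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$n_per_site <- as.integer(table(out$site)[as.character(out$site)])
  endpoint_table(out, level = "tank")
}

#' Write / read endpoint tables
#'
#' Tab-delimited text with a header row; values are written at full double
#' precision so a write/read cycle reproduces the table exactly.
#'
#' @param table An `endpoint_table`.
#' @param path Output (or input) path.
#' @param level Level recorded on reading, `"fish"` or `"tank"`.
#' @return `write_endpoint_table` invisibly returns `path`;
#'   `read_endpoint_table` returns an `endpoint_table`.
#' @export
write_endpoint_table <- function(table, path) {
  stopifnot(inherits(table, "endpoint_table"))
  if (nrow(table) == 0L) {
    warning("write_endpoint_table: writing an empty table (header only)")
  }
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("write_endpoint_table: cannot write to ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' @rdname write_endpoint_table
#' @export
read_endpoint_table <- function(path, level = c("auto", "fish", "tank")) {
  level <- match.arg(level)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = NA)
  for (key in intersect(c("site", "tank_id", "fish_id"), names(df))) {
    df[[key]] <- as.character(df[[key]])
  }
  if (level == "auto") level <- if ("fish_id" %in% names(df)) "fish" else "tank"
  endpoint_table(df, level = level)
}
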