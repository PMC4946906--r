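# Event-annotation CSV I/O. Plain CSV with header
# channel,start_s,end_s,label; "#"-prefixed comment lines (provenance
# headers) are permitted and skipped on read.

#' Write an event table to CSV
#'
#' Events are written sorted by (channel, start) with full numeric
#' precision; column names are `channel,start_s,end_s,label`. Optional
#' comment lines (e.g. seed/config provenance) are prefixed with `#`.
#'
#' @param events an [event_table()] (columns `channel`, `start`, `end`,
#'   `label`).
#' @param path output path.
#' @param comments character vector of comment lines to prepend (without
#'   the leading `#`).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, comments = character()) {
  stopifnot(is.data.frame(events),
            all(c("channel", "start", "end") %in% names(events)))
  if (nrow(events) > 0 && any(events$end <= events$start))
    stop(sprintf("event end must exceed start (row %d)",
                 which(events$end <= events$start)[1L]), call. = FALSE)
  if (!"label" %in% names(events)) events$label <- ""
  events <- events[order(events$channel, events$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines("channel,start_s,end_s,label", con)
  if (nrow(events) > 0)
    writeLines(sprintf("%s,%s,%s,%s", events$channel,
                       format(events$start, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       format(events$end, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       events$label), con)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path CSV path as written by [write_events()] (columns
#'   `channel,start_s,end_s,label`; `#` comment lines ignored).
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "numeric", "numeric",
                                       "character"))
  need <- c("channel", "start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("events CSV must have header channel,start_s,end_s,label",
         call. = FALSE)
  bad <- which(df$end_s <= df$start_s)
  if (length(bad))
    stop(sprintf("event end must exceed start (row %d)", bad[1L]),
         call. = FALSE)
  event_table(df$channel, df$start_s, df$end_s, df$label)
}
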