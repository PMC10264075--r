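#' Read landmark configurations
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tps_text`}{the classic morphometrics TPS text format: records of
#'     `LM3=<n>` followed by n lines of `x y z`, then `ID=<name>` (optional
#'     `SCALE=`, `IMAGE=` lines are ignored).  The format carries no
#'     class/grouping metadata; supply a `template` to attach it.}
#'   \item{`table`}{a flat CSV with columns `specimen_id, point_index, x, y,
#'     z, class, group` (the export layout of point-and-click landmarking
#'     tools).}
#' }
#'
#' @param path file path.
#' @param dialect `"tps_text"` or `"table"`.
#' @param template optional `landmark_config` or `template_definition` whose
#'   classes/groups are attached to dialects that carry none; point counts
#'   must then match.
#' @param element,side metadata applied to configurations when the file
#'   carries none.
#' @return list of `landmark_config` objects (empty, with a warning, for an
#'   empty file).
#' @export
read_landmarks <- function(path, dialect = c("tps_text", "table"),
                           template = NULL,
                           element = "complete_femur", side = "left") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tmpl_cfg <- template_config_or_null(template)
  switch(dialect,
         tps_text = read_tps_text(path, tmpl_cfg, element, side),
         table = read_landmark_table(path, element, side))
}

template_config_or_null <- function(template) {
  if (is.null(template)) return(NULL)
  if (inherits(template, "template_definition")) return(template$template_config)
  if (is_landmark_config(template)) return(template)
  stop("template must be a landmark_config or template_definition")
}

read_tps_text <- function(path, tmpl, element, side) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty landmark file: ", path)
    return(list())
  }
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i], ignore.case = TRUE))
      stop("parse error at line ", i, ": expected LM3=<count>, got '",
           lines[i], "'")
    n <- suppressWarnings(as.integer(sub("^LM3=", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(n) || n < 0) stop("parse error at line ", i, ": bad LM3 count")
    if (i + n > length(lines))
      stop("parse error: record starting at line ", i,
           " truncated (needs ", n, " coordinate lines)")
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[i + k],
                                                   "[ \t]+")[[1]]))
      if (length(vals) != 3L || anyNA(vals))
        stop("parse error at line ", i + k, ": expected 3 coordinates")
      coords[k, ] <- vals
    }
    i <- i + n + 1L
    id <- paste0("record", length(configs) + 1L)
    while (i <= length(lines) && !grepl("^LM3=", lines[i],
                                        ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    if (!is.null(tmpl)) {
      if (nrow(tmpl$points) != n)
        stop("dimension error: record '", id, "' has ", n,
             " points but the template has ", nrow(tmpl$points))
      cls <- tmpl$classes; grp <- tmpl$group
    } else {
      cls <- rep("anatomical", n); grp <- rep(NA_character_, n)
    }
    configs[[length(configs) + 1L]] <-
      landmark_config(coords, cls, specimen_id = id, element = element,
                      side = side, group = grp)
  }
  names(configs) <- vapply(configs, `[[`, character(1), "specimen_id")
  configs
}

read_landmark_table <- function(path, element, side) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("empty landmark table: ", path)
    return(list())
  }
  need <- c("specimen_id", "point_index", "x", "y", "z", "class", "group")
  missing_cols <- setdiff(need[1:5], names(df))
  if (length(missing_cols))
    stop("parse error: landmark table lacks columns ",
         paste(missing_cols, collapse = ", "))
  if (!"class" %in% names(df)) df$class <- "anatomical"
  if (!"group" %in% names(df)) df$group <- NA_character_
  if (!"element" %in% names(df)) df$element <- element
  if (!"side" %in% names(df)) df$side <- side
  split_df <- split(df, factor(df$specimen_id, unique(df$specimen_id)))
  configs <- lapply(split_df, function(d) {
    d <- d[order(d$point_index), ]
    landmark_config(as.matrix(d[, c("x", "y", "z")]), d$class,
                    specimen_id = d$specimen_id[1],
                    element = d$element[1], side = d$side[1],
                    group = d$group)
  })
  names(configs) <- names(split_df)
  configs
}

#' Write landmark configurations
#'
#' @param configs list of `landmark_config` objects (or a single one).
#' @param path output file.
#' @param dialect `"tps_text"` or `"table"` (see [read_landmarks()]).
#' @param digits significant digits written (default 12, ample for the
#'   package-wide 1e-6 round-trip tolerance).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path, dialect = c("tps_text", "table"),
                            digits = 12) {
  dialect <- match.arg(dialect)
  if (is_landmark_config(configs)) configs <- list(configs)
  if (dialect == "tps_text") {
    out <- character(0)
    for (cc in configs) {
      n <- nrow(cc$points)
      out <- c(out, paste0("LM3=", n),
               apply(cc$points, 1, function(r)
                 paste(formatC(r, digits = digits, format = "g"),
                       collapse = " ")),
               paste0("ID=", cc$specimen_id))
    }
    writeLines(out, path)
  } else {
    rows <- lapply(configs, function(cc) {
      data.frame(specimen_id = cc$specimen_id,
                 point_index = seq_len(nrow(cc$points)),
                 x = cc$points[, 1], y = cc$points[, 2], z = cc$points[, 3],
                 class = cc$classes, group = cc$group,
                 element = cc$element, side = cc$side,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}
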