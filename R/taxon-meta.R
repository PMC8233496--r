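# Spatiotemporal meta tags carried in taxon names.
#
# A tag-extraction spec is a delimiter-joined list of reserved field names,
# e.g. "name|country|date" with delimiter "|". Reserved names: name, group,
# continent, country, city, date, year, month, day, time. A "date" field is
# parsed as ISO (YYYY, YYYY-MM, YYYY-MM-DD) or a decimal year and populates
# year/month/day. Unknown positions can be skipped with "-".

.META_FIELDS <- c(
  "name", "group", "continent", "country", "city",
  "date", "year", "month", "day", "time"
)

#' Parse spatiotemporal meta tags from a taxon name
#'
#' @param name taxon name string.
#' @param spec tag-extraction spec, e.g. `"name|country|date"`.
#' @param delim single-character field delimiter (default `"|"`).
#' @return a `taxon_meta` list with components `name`, `group`, `continent`,
#'   `country`, `city`, `year`, `month`, `day`, `time` (unextractable fields
#'   are `NA`) and an attribute `warnings` (character vector, possibly
#'   empty). Malformed components warn rather than fail.
#' @export
#' @examples
#' parse_taxon_meta("hCoV|USA|2021-03-15", "name|country|date")
parse_taxon_meta <- function(name, spec, delim = "|") {
  fields <- strsplit(spec, delim, fixed = TRUE)[[1]]
  bad <- setdiff(setdiff(fields, "-"), .META_FIELDS)
  if (length(bad)) {
    stop("unknown field name(s) in spec: ", paste(bad, collapse = ", "))
  }
  parts <- strsplit(name, delim, fixed = TRUE)[[1]]
  out <- stats::setNames(
    as.list(rep(NA_character_, length(.META_FIELDS))), .META_FIELDS
  )
  out$year <- out$month <- out$day <- NA_integer_
  warnings <- character(0)
  if (length(parts) < length(fields)) {
    warnings <- c(warnings, sprintf(
      "taxon '%s': %d field(s) in name but spec expects %d",
      name, length(parts), length(fields)
    ))
  }
  for (i in seq_along(fields)) {
    f <- fields[i]
    if (f == "-" || i > length(parts)) next
    val <- trimws(parts[i])
    if (!nzchar(val)) next
    if (f == "date") {
      d <- .parse_date_token(val)
      if (is.null(d)) {
        warnings <- c(warnings, sprintf(
          "taxon '%s': malformed date '%s'", name, val
        ))
      } else {
        out$year <- d$year
        out$month <- d$month
        out$day <- d$day
      }
    } else if (f %in% c("year", "month", "day")) {
      v <- suppressWarnings(as.integer(val))
      if (is.na(v)) {
        warnings <- c(warnings, sprintf(
          "taxon '%s': malformed %s '%s'", name, f, val
        ))
      } else {
        out[[f]] <- v
      }
    } else {
      out[[f]] <- val
    }
  }
  # a fully specified calendar date must be valid
  if (!is.na(out$year) && !is.na(out$month) && !is.na(out$day)) {
    iso <- sprintf("%04d-%02d-%02d", out$year, out$month, out$day)
    if (is.na(as.Date(iso, format = "%Y-%m-%d", optional = TRUE))) {
      warnings <- c(warnings, sprintf(
        "taxon '%s': invalid calendar date %s", name, iso
      ))
      out$month <- out$day <- NA_integer_
    }
  }
  structure(out, class = "taxon_meta", warnings = warnings)
}

# Parse one date token into year/month/day plus a decimal-year value.
# Accepts YYYY-MM-DD, YYYY-MM, YYYY and plain decimal years. `pin` controls
# where partial dates fall in their interval: "start" (Jan 1 / day 1, the
# default convention) or "mid".
# Returns NULL when unparseable.
.parse_date_token <- function(x, pin = c("start", "mid")) {
  pin <- match.arg(pin)
  x <- trimws(x)
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)) {
    d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
    if (is.na(d)) return(NULL)
    p <- as.integer(strsplit(x, "-")[[1]])
    return(list(
      year = p[1], month = p[2], day = p[3],
      decimal = .decimal_year(d)
    ))
  }
  if (grepl("^\\d{4}-\\d{1,2}$", x)) {
    p <- as.integer(strsplit(x, "-")[[1]])
    if (p[2] < 1 || p[2] > 12) return(NULL)
    day <- if (pin == "start") 1L else 15L
    d <- as.Date(sprintf("%04d-%02d-%02d", p[1], p[2], day))
    return(list(
      year = p[1], month = p[2], day = NA_integer_,
      decimal = .decimal_year(d)
    ))
  }
  if (grepl("^\\d{4}$", x)) {
    y <- as.integer(x)
    dec <- if (pin == "start") as.numeric(y) else y + 0.5
    return(list(year = y, month = NA_integer_, day = NA_integer_, decimal = dec))
  }
  if (grepl("^\\d{4}\\.\\d+$", x)) {
    v <- as.numeric(x)
    return(list(
      year = as.integer(floor(v)), month = NA_integer_, day = NA_integer_,
      decimal = v
    ))
  }
  NULL
}

# Calendar date -> decimal year: year + (day-of-year - 0.5)/days-in-year.
.decimal_year <- function(d) {
  y <- as.integer(format(d, "%Y"))
  doy <- as.integer(format(d, "%j"))
  diy <- as.integer(format(as.Date(sprintf("%04d-12-31", y)), "%j"))
  y + (doy - 0.5) / diy
}

#' @export
print.taxon_meta <- function(x, ...) {
  cat("taxon_meta:\n")
  for (f in .META_FIELDS) {
    if (f == "date") next
    if (!is.na(x[[f]])) cat(sprintf("  %-9s %s\n", f, x[[f]]))
  }
  w <- attr(x, "warnings")
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}
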