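# Canonical gas-exchange records, response curves, and table ingest/serialisation.

# canonical per-record fields, in canonical column order
GX_FIELDS <- c("I", "Ca", "Cs", "Ci", "An", "gsw", "gsc", "hr", "D", "Tleaf")
GX_LABELS <- c("species", "replicate", "protocol")

#' Convert stomatal conductance to water vapor into conductance to CO2
#'
#' Instruments log conductance to water vapor (gsw); the models here are
#' written for conductance to CO2 (gsc). The two differ by the binary
#' diffusivity ratio of water vapor to CO2 in air, 1.6: `gsc = gsw / 1.6`.
#'
#' @param gsw Conductance to water vapor, mol m-2 s-1 (>= 0).
#' @return Conductance to CO2, mol m-2 s-1.
#' @export
convert_gsw_to_gsc <- function(gsw) {
  if (any(gsw < 0, na.rm = TRUE)) {
    stop("gsw must be non-negative", call. = FALSE)
  }
  gsw / 1.6
}

#' Construct a response curve
#'
#' A response curve is an ordered set of gas-exchange records for one
#' species x replicate x protocol: a light-response curve (irradiance varied
#' at constant ambient CO2), a CO2-response curve (ambient CO2 varied at
#' constant irradiance), or a free design grid (used by the noise-free
#' generators for fitting experiments).
#'
#' Record invariants are validated: non-negative I, CO2 concentrations and
#' conductances; `gsw = 1.6 * gsc` to 1e-9 when both are present (the missing
#' one is derived otherwise); `hr` in `[0, 1]`; `D > 0`; and `Ci > Ca` only
#' where `An < 0` (net efflux).
#'
#' @param species Species label.
#' @param replicate Replicate identifier.
#' @param protocol_kind `"light"`, `"co2"`, or `"design"`.
#' @param data Data frame of records with canonical columns (any subset of
#'   `I, Ca, Cs, Ci, An, gsw, gsc, hr, D, Tleaf`); row order is the
#'   measurement order and is preserved.
#' @param ambient Named list of fixed conditions (e.g. `Ca` for light curves,
#'   `I` for CO2 curves).
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(species, replicate,
                           protocol_kind = c("light", "co2", "design"),
                           data, ambient = list()) {
  protocol_kind <- match.arg(protocol_kind)
  data <- as.data.frame(data)
  if (nrow(data) < 3L) {
    stop("a response curve needs at least 3 records, got ", nrow(data),
         call. = FALSE)
  }
  unknown <- setdiff(names(data), GX_FIELDS)
  if (length(unknown) > 0L) {
    stop("unknown record field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  data <- .complete_conductances(data)
  .validate_records(data)
  if (protocol_kind == "light" && !is.null(data$Ca) &&
      diff(range(data$Ca)) > 0.05 * max(abs(data$Ca), 1)) {
    warning("light-response curve with non-constant Ca", call. = FALSE)
  }
  if (protocol_kind == "co2" && !is.null(data$I) &&
      diff(range(data$I)) > 1e-6) {
    stop("CO2-response curve must hold irradiance constant", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(
    list(species = as.character(species), replicate = as.character(replicate),
         protocol_kind = protocol_kind, data = data, ambient = ambient),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %s / %s (%s): %d records [%s]\n",
              x$species, x$replicate, x$protocol_kind, nrow(x$data),
              paste(names(x$data), collapse = ", ")))
  invisible(x)
}

# derive whichever of gsw/gsc is absent; check the 1.6 ratio when both present
.complete_conductances <- function(data) {
  has_gsw <- "gsw" %in% names(data)
  has_gsc <- "gsc" %in% names(data)
  if (!has_gsw && !has_gsc) {
    stop("records must carry gsw or gsc", call. = FALSE)
  }
  if (has_gsw && !has_gsc) data$gsc <- convert_gsw_to_gsc(data$gsw)
  if (has_gsc && !has_gsw) data$gsw <- 1.6 * data$gsc
  data
}

.validate_records <- function(data) {
  chk <- function(cond, msg) {
    bad <- which(!cond & !is.na(cond))
    if (length(bad) > 0L) {
      stop("record invariant violated (", msg, ") in record(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(data$I)) chk(data$I >= 0, "I >= 0")
  for (cc in c("Ca", "Cs", "Ci")) {
    if (!is.null(data[[cc]])) chk(data[[cc]] >= 0, paste(cc, ">= 0"))
  }
  chk(data$gsc >= 0, "gsc >= 0")
  chk(abs(data$gsw - 1.6 * data$gsc) <= 1e-9 * pmax(1, abs(data$gsw)),
      "gsw = 1.6 gsc")
  if (!is.null(data$hr)) chk(data$hr >= 0 & data$hr <= 1, "hr in [0, 1]")
  if (!is.null(data$D)) chk(data$D > 0, "D > 0")
  if (!is.null(data$Ci) && !is.null(data$Ca) && !is.null(data$An)) {
    chk(!(data$Ci > data$Ca + 1e-9 & data$An >= 0),
        "Ci > Ca only permitted when An < 0")
  }
  invisible(data)
}

#' Bundled LI-6400 header map
#'
#' Maps LI-6400 log headers onto the canonical column names
#' (`Photo -> An`, `Cond -> gsw`, `CO2S -> Cs`, `CO2R -> Ca`, `RH_S -> hr`,
#' `VpdL -> D`, `PARi -> I`). The relative-humidity column is flagged
#' percent-scaled and is divided by 100 at ingest.
#'
#' @return A column map: list with elements `columns` (named character,
#'   canonical name -> file header) and `percent` (canonical names logged in
#'   percent).
#' @export
li6400_column_map <- function() {
  list(
    columns = c(species = "species", replicate = "replicate",
                protocol = "protocol",
                An = "Photo", gsw = "Cond", Ci = "Ci", Cs = "CO2S",
                Ca = "CO2R", hr = "RH_S", D = "VpdL", I = "PARi",
                Tleaf = "Tleaf"),
    percent = "hr"
  )
}

#' Identity column map for canonical headers
#' @return A column map (see [li6400_column_map()]).
#' @export
canonical_column_map <- function() {
  nm <- c(GX_LABELS, GX_FIELDS)
  list(columns = setNames(nm, nm), percent = character(0))
}

#' Read a column map from a YAML or JSON config file
#'
#' The file holds a `columns` mapping (canonical name -> file header) and an
#' optional `percent` list of canonical names whose values are logged in
#' percent.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A column map (see [li6400_column_map()]).
#' @export
read_column_map <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$columns)) stop("column-map config lacks 'columns'", call. = FALSE)
  list(columns = unlist(cfg$columns),
       percent = as.character(cfg$percent %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gas-exchange table into response curves
#'
#' Reads an RFC-4180 CSV of logged observations (one row each), renames
#' columns through `column_map`, scales percent-logged columns to fractions,
#' derives `gsc` from `gsw` (or vice versa), and groups rows into
#' [response_curve()] objects by (species, replicate, protocol), preserving
#' file row order within each curve (measurement protocols are ordered
#' sequences). A missing `Cs` column falls back to `Ca` (leaf-surface CO2
#' approximated by ambient) with a warning.
#'
#' @param path CSV file path.
#' @param column_map A column map (see [li6400_column_map()]); defaults to
#'   canonical headers.
#' @return List of `response_curve` objects, in order of first appearance.
#' @export
read_gas_exchange_table <- function(path, column_map = canonical_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(column_map)) {
    column_map <- list(columns = column_map, percent = character(0))
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cm <- column_map$columns
  present <- cm[cm %in% names(raw)]
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)

  for (lab in GX_LABELS) {
    if (!lab %in% names(df)) {
      stop("missing mandatory column: ", lab,
           " (mapped from '", cm[[lab]] %||% lab, "')", call. = FALSE)
    }
  }
  if (!any(c("gsw", "gsc") %in% names(df))) {
    stop("missing mandatory column: need gsw or gsc (mapped from '",
         cm[["gsw"]] %||% "gsw", "' or '", cm[["gsc"]] %||% "gsc", "')",
         call. = FALSE)
  }
  for (col in c("An", "Ca")) {
    if (!col %in% names(df)) {
      stop("missing mandatory column: ", col, call. = FALSE)
    }
  }

  num_cols <- intersect(GX_FIELDS, names(df))
  for (col in num_cols) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s', file row %d",
                   v[bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    }
    df[[col]] <- num
  }
  for (col in intersect(column_map$percent, num_cols)) {
    df[[col]] <- df[[col]] / 100
  }
  if (!"Cs" %in% names(df)) {
    warning("no Cs column: approximating leaf-surface CO2 by ambient Ca",
            call. = FALSE)
    df$Cs <- df$Ca
  }

  proto <- tolower(trimws(as.character(df$protocol)))
  proto[proto %in% c("light", "an-i", "a-i", "i")] <- "light"
  proto[proto %in% c("co2", "an-ci", "a-ci", "aci")] <- "co2"

  key <- paste(df$species, df$replicate, proto, sep = "\r")
  curves <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    if (nrow(rows) < 3L) {
      warning("skipping group ", parts[1L], "/", parts[2L], "/", parts[3L],
              ": fewer than 3 records", call. = FALSE)
      next
    }
    curves[[length(curves) + 1L]] <- response_curve(
      species = parts[1L], replicate = parts[2L], protocol_kind = parts[3L],
      data = rows[, intersect(GX_FIELDS, names(rows)), drop = FALSE]
    )
  }
  curves
}

#' Write response curves to a canonical gas-exchange CSV
#'
#' Serialises curves to the canonical table layout read back by
#' [read_gas_exchange_table()]; numeric fields round-trip to at least 6
#' significant digits (full double precision is written).
#'
#' @param curves A `response_curve` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_table <- function(curves, path) {
  if (inherits(curves, "response_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    cbind(data.frame(species = cv$species, replicate = cv$replicate,
                     protocol = cv$protocol_kind,
                     stringsAsFactors = FALSE),
          cv$data)
  })
  all_cols <- c(GX_LABELS, intersect(GX_FIELDS,
                                     unique(unlist(lapply(rows, names)))))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA_real_
    r[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a model-comparison table to CSV or JSON
#'
#' One row per (species, model) with replicate-aggregated parameters,
#' significance letters, and pooled diagnostics. Reading the file back with
#' [read_fit_report()] reproduces all numeric fields to at least 6
#' significant digits.
#'
#' @param table A `comparison_table` (see [build_comparison_table()]) or a
#'   data frame in its row layout.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- if (inherits(table, "comparison_table")) table$rows else as.data.frame(table)
  meta <- if (inherits(table, "comparison_table")) {
    list(condition = table$condition, alpha = table$alpha)
  } else NULL
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(list(metadata = meta, rows = rows), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a model-comparison report written by [write_fit_report()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A data frame of report rows.
#' @export
read_fit_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    as.data.frame(out$rows)
  }
}
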