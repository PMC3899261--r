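#' Column-name schema for Ct CSV files
#'
#' @param sample,group,region,replicate,ct column names in the file.
#' @param rt_primer optional column with the reverse-transcription primer.
#' @param undetermined token marking wells with no amplification.
#' @return A named list used by [read_ct_table()].
#' @export
ct_schema <- function(sample = "sample_id", group = "group_id", region = "region",
                      replicate = "replicate", ct = "ct",
                      rt_primer = "rt_primer", undetermined = "Undetermined") {
  list(sample = sample, group = group, region = region, replicate = replicate,
       ct = ct, rt_primer = rt_primer, undetermined = undetermined)
}

#' Read a long-format Ct table from delimited text
#'
#' Expects one row per well.  Lines starting with `#` are treated as
#' comments; `#mask: group,region` comment lines (as written by
#' [write_ct_table()]) repopulate the stability mask.
#'
#' @param path CSV file path.
#' @param schema a [ct_schema()] mapping file columns to fields.
#' @param max_cycles passed to [ct_table()].
#' @return A validated [ct_table()].
#' @export
read_ct_table <- function(path, schema = ct_schema(), max_cycles = 40) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  need <- c(sample = schema$sample, group = schema$group, region = schema$region,
            replicate = schema$replicate, ct = schema$ct)
  miss <- need[!need %in% names(df)]
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  ct_raw <- trimws(df[[schema$ct]])
  ct <- suppressWarnings(as.numeric(ct_raw))
  und <- ct_raw == schema$undetermined
  bad <- is.na(ct) & !und & nzchar(ct_raw)
  if (any(bad))
    stop(sprintf("non-numeric Ct value '%s' at data row %d", ct_raw[which(bad)[1]],
                 which(bad)[1]), call. = FALSE)
  ct[und] <- NA_real_

  wells <- data.frame(sample_id = df[[schema$sample]], group_id = df[[schema$group]],
                      region = df[[schema$region]],
                      replicate = as.integer(df[[schema$replicate]]),
                      ct = ct, stringsAsFactors = FALSE)
  if (schema$rt_primer %in% names(df)) wells$rt_primer <- df[[schema$rt_primer]]
  if ("tm" %in% names(df)) wells$tm <- suppressWarnings(as.numeric(df$tm))

  mask_lines <- sub("^#mask:\\s*", "", grep("^#mask:", comments, value = TRUE))
  mask <- NULL
  if (length(mask_lines)) {
    parts <- strsplit(mask_lines, ",")
    mask <- data.frame(group_id = trimws(vapply(parts, `[`, "", 1)),
                       region = trimws(vapply(parts, `[`, "", 2)),
                       stringsAsFactors = FALSE)
  }
  ct_table(wells, mask = mask, max_cycles = max_cycles)
}

#' Write a Ct table to CSV
#'
#' Emits a `# refstab <version>` header comment, one `#mask:` comment per
#' masked (group, region) pair, and full-precision Ct values so that
#' `read_ct_table(write_ct_table(x))` round-trips exactly.
#'
#' @param table a [ct_table()].
#' @param path output file path.
#' @param undetermined token used for undetermined wells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path, undetermined = "Undetermined") {
  stopifnot(inherits(table, "ct_table"))
  w <- table$wells
  if (!"rt_primer" %in% names(w))
    w$rt_primer <- table$samples$rt_primer[match(w$sample_id, table$samples$sample_id)]
  ct_chr <- ifelse(is.na(w$ct), undetermined, sprintf("%.17g", w$ct))
  header <- c(sprintf("# refstab %s", as.character(utils::packageVersion("refstab"))),
              if (nrow(table$mask))
                sprintf("#mask: %s,%s", table$mask$group_id, table$mask$region))
  body <- c("sample_id,group_id,region,replicate,ct,rt_primer",
            sprintf("%s,%s,%s,%d,%s,%s", w$sample_id, w$group_id, w$region,
                    w$replicate, ct_chr,
                    ifelse(is.na(w$rt_primer), "", w$rt_primer)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a dilution-series table for standard curves
#'
#' @param path CSV with columns `region`, `quantity`, `replicate`, `ct`.
#' @return data frame suitable for [fit_standard_curves()].
#' @export
read_dilution_series <- function(path) {
  lines <- readLines(path)
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  need <- c("region", "quantity", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$region <- as.character(df$region)
  df$quantity <- as.numeric(df$quantity)
  df$ct <- as.numeric(df$ct)
  df
}
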