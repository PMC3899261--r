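#' Well-level threshold-cycle (Ct) table
#'
#' The central data container: one row per (sample, gene region, replicate
#' well).  Undetermined wells (no amplification within `max_cycles` cycles)
#' are stored as `NA` so they stay distinct from absent rows.  A mask of
#' (group, region) pairs can flag cells that should be excluded from
#' stability ranking while remaining available to quantification -- the
#' treatment applied to flower-bud samples assayed with CDS primers after a
#' different reverse-transcription priming strategy.
#'
#' @param wells data frame with columns `sample_id`, `group_id`, `region`,
#'   `replicate`, `ct` (numeric cycles or `NA` for undetermined).  An
#'   optional `rt_primer` column records the reverse-transcription primer.
#' @param samples optional sample sheet (`sample_id`, `group_id`,
#'   `rt_primer`); derived from `wells` when omitted.
#' @param mask optional data frame of (`group_id`, `region`) pairs excluded
#'   from stability ranking.
#' @param max_cycles number of PCR cycles run; Ct values must lie in
#'   `(0, max_cycles]`.  Default 40.
#' @return An object of class `ct_table`.
#' @seealso [read_ct_table()], [collapse_replicates()], [apply_mask()]
#' @export
ct_table <- function(wells, samples = NULL, mask = NULL, max_cycles = 40) {
  wells <- as.data.frame(wells)
  req <- c("sample_id", "group_id", "region", "replicate", "ct")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  wells$sample_id <- as.character(wells$sample_id)
  wells$group_id  <- as.character(wells$group_id)
  wells$region    <- as.character(wells$region)
  wells$replicate <- as.integer(wells$replicate)
  wells$ct        <- as.numeric(wells$ct)
  if (any(wells$replicate < 1L, na.rm = TRUE))
    stop("replicate indices must be >= 1", call. = FALSE)
  bad <- !is.na(wells$ct) & (wells$ct <= 0 | wells$ct > max_cycles)
  if (any(bad))
    stop(sprintf("Ct values must lie in (0, %s] or be undetermined; %d value(s) out of range",
                 format(max_cycles), sum(bad)), call. = FALSE)
  grp_per_sample <- tapply(wells$group_id, wells$sample_id, function(g) length(unique(g)))
  if (any(grp_per_sample > 1))
    stop("sample(s) assigned to more than one group: ",
         paste(names(grp_per_sample)[grp_per_sample > 1], collapse = ", "), call. = FALSE)

  if (is.null(samples)) {
    samples <- unique(wells[, intersect(c("sample_id", "group_id", "rt_primer"), names(wells))])
    if (is.null(samples$rt_primer)) samples$rt_primer <- NA_character_
    rownames(samples) <- NULL
  } else {
    samples <- as.data.frame(samples)
    if (!all(c("sample_id", "group_id") %in% names(samples)))
      stop("sample sheet needs columns sample_id, group_id", call. = FALSE)
    if (is.null(samples$rt_primer)) samples$rt_primer <- NA_character_
    unknown <- setdiff(wells$sample_id, samples$sample_id)
    if (length(unknown))
      stop("well rows reference unknown sample(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  samples$rt_primer <- as.character(samples$rt_primer)
  ok_primer <- is.na(samples$rt_primer) |
    samples$rt_primer %in% c("oligo_dT", "random_hexamer")
  if (!all(ok_primer))
    stop("rt_primer must be 'oligo_dT' or 'random_hexamer'", call. = FALSE)

  x <- structure(
    list(wells = wells, samples = samples,
         mask = empty_mask(), max_cycles = max_cycles, collapsed = FALSE),
    class = "ct_table")
  if (!is.null(mask) && nrow(as.data.frame(mask))) x <- apply_mask(x, mask)
  x
}

empty_mask <- function() data.frame(group_id = character(), region = character(),
                                    stringsAsFactors = FALSE)

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d wells | %d samples in %d groups | %d regions%s\n",
              nrow(x$wells), nrow(x$samples), length(unique(x$samples$group_id)),
              length(unique(x$wells$region)),
              if (x$collapsed) " | collapsed" else ""))
  if (nrow(x$mask))
    cat("  mask:", paste(x$mask$group_id, x$mask$region, sep = "/", collapse = ", "), "\n")
  nund <- sum(is.na(x$wells$ct))
  if (nund) cat(sprintf("  %d undetermined well(s)\n", nund))
  invisible(x)
}

#' Flag (group, region) cells as excluded from stability ranking
#'
#' Masking is flag-only: Ct values are kept and remain available to
#' quantification operations, but stability algorithms skip the flagged
#' cells (pairwise-complete analysis).
#'
#' @param table a [ct_table()].
#' @param pairs data frame with columns `group_id` and `region`.
#' @return The table with its mask extended.
#' @export
apply_mask <- function(table, pairs) {
  stopifnot(inherits(table, "ct_table"))
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) return(table)
  if (!all(c("group_id", "region") %in% names(pairs)))
    stop("mask needs columns group_id, region", call. = FALSE)
  pairs$group_id <- as.character(pairs$group_id)
  pairs$region <- as.character(pairs$region)
  bad_g <- setdiff(pairs$group_id, table$samples$group_id)
  if (length(bad_g)) stop("mask references unknown group(s): ",
                          paste(bad_g, collapse = ", "), call. = FALSE)
  bad_r <- setdiff(pairs$region, table$wells$region)
  if (length(bad_r)) stop("mask references unknown region(s): ",
                          paste(bad_r, collapse = ", "), call. = FALSE)
  m <- unique(rbind(table$mask, pairs[, c("group_id", "region")]))
  rownames(m) <- NULL
  table$mask <- m
  table
}

#' Collapse replicate wells to one Ct per (sample, region)
#'
#' Undetermined wells are excluded from the aggregate; a cell whose wells
#' are all undetermined collapses to undetermined.  Cells whose well range
#' exceeds `max_spread` cycles are retained but flagged (`qc_spread`).
#'
#' @param table a [ct_table()].
#' @param policy `"mean"` (default, the conventional per-run mean Ct) or
#'   `"median"` for robustness to a single aberrant well.
#' @param max_spread QC threshold on the within-cell well range, in cycles.
#' @return A collapsed `ct_table` (one row per sample x region) whose wells
#'   carry a logical `qc_spread` column.
#' @export
collapse_replicates <- function(table, policy = c("mean", "median"), max_spread = 1) {
  stopifnot(inherits(table, "ct_table"))
  policy <- match.arg(policy)
  if (!is.numeric(max_spread) || max_spread <= 0)
    stop("max_spread must be > 0", call. = FALSE)
  agg <- if (policy == "mean") mean else stats::median
  w <- table$wells
  key <- interaction(w$sample_id, w$region, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(w)), key), function(i) {
    ct <- w$ct[i]
    obs <- ct[!is.na(ct)]
    data.frame(sample_id = w$sample_id[i[1]], group_id = w$group_id[i[1]],
               region = w$region[i[1]], replicate = 1L,
               ct = if (length(obs)) agg(obs) else NA_real_,
               qc_spread = length(obs) > 1 && diff(range(obs)) > max_spread,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, out$region), ]
  rownames(out) <- NULL
  table$wells <- out
  table$collapsed <- TRUE
  table
}

#' Merge two independent analytical runs
#'
#' Runs repeated on the same samples and regions are consolidated by
#' averaging their collapsed Ct values (an undetermined cell in one run
#' falls back to the other run's value).
#'
#' @param a,b collapsed [ct_table()] objects covering the same cells.
#' @return A collapsed `ct_table` of per-cell mean Cts.
#' @export
merge_runs <- function(a, b) {
  stopifnot(inherits(a, "ct_table"), inherits(b, "ct_table"))
  if (!a$collapsed || !b$collapsed)
    stop("merge_runs expects collapsed tables; see collapse_replicates()", call. = FALSE)
  ka <- paste(a$wells$sample_id, a$wells$region)
  kb <- paste(b$wells$sample_id, b$wells$region)
  if (!setequal(ka, kb))
    stop("runs cover different (sample, region) cells", call. = FALSE)
  bb <- b$wells[match(ka, kb), ]
  ct <- rowMeans(cbind(a$wells$ct, bb$ct), na.rm = TRUE)
  ct[is.nan(ct)] <- NA_real_
  a$wells$ct <- ct
  a$wells$qc_spread <- a$wells$qc_spread | bb$qc_spread
  a$mask <- unique(rbind(a$mask, b$mask))
  rownames(a$mask) <- NULL
  a
}

#' Collapsed Ct values as a samples x regions matrix
#'
#' The matrix carries `groups` (named sample-to-group map) and `mask`
#' (logical matrix, TRUE = excluded from stability ranking) attributes that
#' downstream stability functions honour.
#'
#' @param table a collapsed [ct_table()] (well-level input is collapsed
#'   with the default mean policy first).
#' @return numeric matrix of Cts with attributes `groups` and `mask`.
#' @export
ct_matrix <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  if (!table$collapsed) table <- collapse_replicates(table)
  w <- table$wells
  samples <- sort(unique(w$sample_id))
  regions <- sort(unique(w$region))
  m <- matrix(NA_real_, length(samples), length(regions),
              dimnames = list(samples, regions))
  m[cbind(match(w$sample_id, samples), match(w$region, regions))] <- w$ct
  groups <- stats::setNames(table$samples$group_id, table$samples$sample_id)[samples]
  mask <- matrix(FALSE, length(samples), length(regions),
                 dimnames = dimnames(m))
  if (nrow(table$mask)) {
    for (i in seq_len(nrow(table$mask))) {
      g <- table$mask$group_id[i]; r <- table$mask$region[i]
      if (r %in% regions) mask[groups == g, r] <- TRUE
    }
  }
  attr(m, "groups") <- groups
  attr(m, "mask") <- mask
  m
}
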