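# Internal helpers shared across modules.

# Geometric mean; NA if any component missing, error on non-positive values.
geo_mean <- function(x) {
  if (anyNA(x)) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

# gene symbol from a "GENE_region" display name
region_gene <- function(region) sub("_.*$", "", region)

region_label <- function(region) {
  lab <- sub("^[^_]*_?", "", region)
  ifelse(nzchar(lab), lab, "utr")
}

is_cds_region <- function(region) region_label(region) == "cds"

# log2 quantities with masked cells set to NA.  `q` is a samples x regions
# matrix carrying an optional logical "mask" attribute of the same shape.
log2_quantities <- function(q) {
  m <- attr(q, "mask")
  L <- log2(as_quantity_matrix(q))
  if (!is.null(m)) L[m] <- NA_real_
  L
}

# Coerce to a plain numeric matrix with sample/region dimnames, checking
# positivity of observed cells.
as_quantity_matrix <- function(q) {
  if (is.data.frame(q)) q <- as.matrix(q)
  if (!is.matrix(q) || !is.numeric(q))
    stop("quantities must be a numeric samples x regions matrix", call. = FALSE)
  if (is.null(colnames(q)))
    colnames(q) <- paste0("region", seq_len(ncol(q)))
  if (is.null(rownames(q)))
    rownames(q) <- paste0("sample", seq_len(nrow(q)))
  if (any(q[!is.na(q)] <= 0))
    stop("all observed quantities must be strictly positive", call. = FALSE)
  q
}

# Sample groups for a quantity matrix: explicit argument wins, else the
# "groups" attribute attached by quantify()/ct_matrix().
resolve_groups <- function(q, groups = NULL) {
  if (is.null(groups)) groups <- attr(q, "groups")
  if (is.null(groups)) return(NULL)
  if (is.null(names(groups))) {
    if (length(groups) != nrow(q))
      stop("`groups` must be named by sample or match nrow(q)", call. = FALSE)
    names(groups) <- rownames(q)
  }
  missing <- setdiff(rownames(q), names(groups))
  if (length(missing))
    stop("no group assignment for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.character(groups[rownames(q)])
}
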