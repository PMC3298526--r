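#' Read a gene-by-sample numeric matrix
#'
#' Reads a tab-delimited matrix (first column gene identifiers, header row of
#' sample identifiers) and enforces the invariants of its kind. Rows with any
#' missing cell are dropped with a message; duplicate gene rows are collapsed
#' by their per-gene mean; gene symbols are uppercased.
#'
#' Kinds and their range constraints:
#' \describe{
#'   \item{expression}{nonnegative continuous values on an RMA-like scale;
#'     negative rows are dropped with a message.}
#'   \item{cnv}{finite log2 copy-number ratios (0 = diploid).}
#'   \item{methylation}{beta values; any value outside \[0, 1\] is an error.}
#' }
#'
#' @param path path to a tab-delimited file.
#' @param kind one of `"expression"`, `"cnv"`, `"methylation"`.
#' @return a numeric matrix (genes in rows, samples in columns) with a
#'   `"kind"` attribute.
#' @export
read_matrix <- function(path, kind = c("expression", "cnv", "methylation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("format error: expected a tab-delimited header with sample columns in ",
         path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(raw) < 2L) stop("format error: no sample columns in ", path)
  genes <- toupper(as.character(raw[[1L]]))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop("parse error: non-numeric cell at gene '", genes[bad],
           "', sample '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  keep <- stats::complete.cases(m)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing values")
    m <- m[keep, , drop = FALSE]
  }
  m <- collapse_duplicate_genes(m)
  validate_matrix(m, kind)
}

#' Collapse duplicate gene rows by per-gene mean
#'
#' @param m numeric matrix with gene rownames.
#' @return matrix with unique rownames; duplicated genes averaged.
#' @export
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  g <- factor(rownames(m), levels = unique(rownames(m)))
  out <- rowsum(m, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

validate_matrix <- function(m, kind) {
  if (!is.matrix(m) || !is.numeric(m)) stop("matrix of numeric values required")
  if (anyNA(m)) stop("missing values present after load")
  if (kind == "methylation") {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("range error: methylation beta outside [0,1] at gene '",
           rownames(m)[bad[1L, 1L]], "', sample '", colnames(m)[bad[1L, 2L]],
           "' (value ", format(m[bad[1L, , drop = FALSE]]), ")")
  }
  if (kind == "cnv" && any(!is.finite(m)))
    stop("range error: non-finite cnv log-ratio")
  if (kind == "expression") {
    neg <- apply(m, 1L, function(r) any(r < 0))
    if (any(neg)) {
      message(sum(neg), " expression row(s) dropped for negative values")
      m <- m[!neg, , drop = FALSE]
    }
  }
  structure(m, kind = kind)
}

#' Write a gene-by-sample matrix as tab-delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(x))` round-trips doubles exactly.
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  fmt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(fmt, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Expects tab-delimited columns `sample_id`, `time` (days, strictly
#' positive) and `event` (1 = death observed, 0 = right-censored).
#'
#' @param path path to the file.
#' @return a `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  d <- d[, need]
  d$sample_id <- as.character(d$sample_id)
  validate_clinical(d)
}

validate_clinical <- function(d) {
  dup <- unique(d$sample_id[duplicated(d$sample_id)])
  if (length(dup) > 0L)
    stop("validation error: duplicate sample_id: ", paste(dup, collapse = ", "))
  bad_t <- d$sample_id[!is.finite(d$time) | d$time <= 0]
  if (length(bad_t) > 0L)
    stop("validation error: non-positive survival time for: ",
         paste(bad_t, collapse = ", "))
  bad_e <- d$sample_id[!(d$event %in% c(0, 1))]
  if (length(bad_e) > 0L)
    stop("validation error: event not in {0,1} for: ",
         paste(bad_e, collapse = ", "))
  d$event <- as.integer(d$event)
  class(d) <- c("clinical_table", "data.frame")
  d
}

#' Write a clinical table
#' @param d clinical table (`sample_id`, `time`, `event`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(d, path) {
  utils::write.table(d[, c("sample_id", "time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pathway set from interaction records
#'
#' A pathway is a list of interactions; each interaction has promoter
#' and/or inhibitor input genes and optional output genes. Gene symbols are
#' uppercased.
#'
#' @param records data.frame with columns `pathway_id`, `interaction_id`,
#'   `gene`, `role` (one of `"promoter"`, `"inhibitor"`, `"output"`), and
#'   optionally `pathway_name`.
#' @return an object of class `pathway_set`.
#' @export
pathway_set <- function(records) {
  need <- c("pathway_id", "interaction_id", "gene", "role")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(records$role), c("promoter", "inhibitor", "output"))
  if (length(bad_role) > 0L)
    stop("format error: unknown role token(s): ",
         paste(bad_role, collapse = ", "))
  records$gene <- toupper(as.character(records$gene))
  pw_ids <- unique(as.character(records$pathway_id))
  names_map <- stats::setNames(pw_ids, pw_ids)
  if ("pathway_name" %in% names(records)) {
    nm <- tapply(as.character(records$pathway_name), records$pathway_id,
                 function(v) v[1L])
    names_map[names(nm)] <- nm
  }
  pathways <- lapply(pw_ids, function(pid) {
    rec <- records[records$pathway_id == pid, ]
    if (nrow(rec) == 0L) stop("format error: empty pathway block: ", pid)
    int_ids <- unique(rec$interaction_id)
    ints <- lapply(int_ids, function(iid) {
      r <- rec[rec$interaction_id == iid, ]
      it <- list(id = as.character(iid),
                 promoters = r$gene[r$role == "promoter"],
                 inhibitors = r$gene[r$role == "inhibitor"],
                 outputs = r$gene[r$role == "output"])
      if (length(it$promoters) + length(it$inhibitors) == 0L)
        stop("format error: interaction '", iid, "' in pathway '", pid,
             "' has no input genes")
      it
    })
    names(ints) <- int_ids
    ints
  })
  names(pathways) <- pw_ids
  if (any(vapply(pathways, length, 1L) == 0L))
    stop("format error: pathway with no interactions")
  structure(list(pathways = pathways, names = names_map),
            class = "pathway_set")
}

#' Read a pathway interaction file
#'
#' Tab-delimited with header `pathway_id`, `interaction_id`, `gene`, `role`
#' (one row per gene slot per interaction); an optional `pathway_name`
#' column supplies display names.
#'
#' @param path path to the file.
#' @return a `pathway_set`.
#' @export
read_pathway_set <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  pathway_set(d)
}

#' Write a pathway set in the tab-delimited interaction dialect
#' @param ps a `pathway_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_set <- function(ps, path) {
  rows <- do.call(rbind, lapply(names(ps$pathways), function(pid) {
    do.call(rbind, lapply(ps$pathways[[pid]], function(it) {
      role <- c(rep("promoter", length(it$promoters)),
                rep("inhibitor", length(it$inhibitors)),
                rep("output", length(it$outputs)))
      data.frame(pathway_id = pid, interaction_id = it$id,
                 gene = c(it$promoters, it$inhibitors, it$outputs),
                 role = role, pathway_name = ps$names[[pid]],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway identifiers of a pathway set
#' @param ps a `pathway_set`.
#' @return character vector of pathway ids.
#' @export
pathway_ids <- function(ps) names(ps$pathways)

#' Member genes of one pathway
#' @param ps a `pathway_set`.
#' @param pathway_id pathway identifier.
#' @return character vector of unique member genes (inputs and outputs).
#' @export
pathway_genes <- function(ps, pathway_id) {
  ints <- ps$pathways[[pathway_id]]
  if (is.null(ints)) stop("unknown pathway: ", pathway_id)
  sort(unique(unlist(lapply(ints, function(it)
    c(it$promoters, it$inhibitors, it$outputs)))))
}

#' @export
print.pathway_set <- function(x, ...) {
  n_int <- vapply(x$pathways, length, 1L)
  cat("pathway_set:", length(x$pathways), "pathways,",
      sum(n_int), "interactions\n")
  invisible(x)
}

# Intersect the sample universe of a matrix and a clinical table, with a
# message so dropped samples are visible in logs.
align_samples <- function(m, clinical) {
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) == 0L) stop("no samples shared with clinical table")
  dropped <- ncol(m) - length(common)
  if (dropped > 0L)
    message(dropped, " sample(s) without clinical data excluded")
  list(m = m[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample_id), , drop = FALSE])
}
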