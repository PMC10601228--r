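#' Construct a clinical covariate table
#'
#' A `clinical_table` holds an n x q table of mixed continuous/categorical
#' covariates with one row per subject, keyed by a subject identifier. It is
#' the input to the embedding step and supplies the adjustment covariates of
#' the null model. Missing values are rejected: the methods here assume
#' complete, pre-processed covariates, and silent imputation is a worse
#' failure mode than a loud error.
#'
#' @param data data.frame of covariates (without the id column).
#' @param subject_id character vector of unique subject identifiers.
#' @param types named character vector mapping each column of `data` to
#'   `"continuous"` or `"categorical"`. Columns not named default to
#'   `"categorical"` for factors/characters and `"continuous"` otherwise.
#' @return An object of class `clinical_table`: a data.frame with attributes
#'   `subject_id` and `types`.
#' @export
clinical_table <- function(data, subject_id = rownames(data), types = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) < 2L) stop("a clinical table needs at least 2 subjects")
  if (is.null(subject_id)) subject_id <- as.character(seq_len(nrow(data)))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicated subject ids")
  if (length(subject_id) != nrow(data)) stop("subject_id length != nrow(data)")
  if (anyNA(data)) {
    bad <- names(data)[vapply(data, anyNA, logical(1))]
    stop("missing values in clinical columns: ", paste(bad, collapse = ", "))
  }
  full <- stats::setNames(
    ifelse(vapply(data, function(x) is.factor(x) || is.character(x), logical(1)),
           "categorical", "continuous"),
    names(data))
  if (!is.null(types)) {
    unknown <- setdiff(names(types), names(data))
    if (length(unknown))
      stop("type map names columns not present: ", paste(unknown, collapse = ", "))
    if (!all(types %in% c("continuous", "categorical")))
      stop("types must be 'continuous' or 'categorical'")
    full[names(types)] <- types
  }
  for (nm in names(data)) {
    if (full[[nm]] == "categorical") {
      data[[nm]] <- factor(data[[nm]])
      if (nlevels(data[[nm]]) < 2L)
        stop("categorical column '", nm, "' has fewer than 2 levels")
    } else {
      if (!is.numeric(data[[nm]]))
        stop("column '", nm, "' typed continuous but is not numeric")
    }
  }
  structure(data, subject_id = subject_id, types = full,
            class = c("clinical_table", "data.frame"))
}

#' Read a clinical table from a delimited file
#'
#' @param path CSV or TSV file with a header row and a subject-id column.
#' @param type_map named character vector assigning `"continuous"` or
#'   `"categorical"` to covariate columns (see [clinical_table()]).
#' @param id_col name of the subject-id column (default `"subject_id"`).
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @return A [clinical_table()].
#' @export
load_clinical <- function(path, type_map = NULL, id_col = "subject_id",
                          sep = NULL) {
  df <- read_delim_guess(path, sep)
  if (!id_col %in% names(df))
    stop("subject id column '", id_col, "' not found in ", path)
  ids <- as.character(df[[id_col]])
  df[[id_col]] <- NULL
  clinical_table(df, subject_id = ids, types = type_map)
}

#' Construct an omics abundance matrix
#'
#' @param values numeric n x m matrix, rows aligned to subjects.
#' @param subject_id subject identifiers (length n).
#' @param feature_names feature labels (length m).
#' @return An `omics_matrix`: a numeric matrix with a `subject_id` attribute.
#' @export
omics_matrix <- function(values, subject_id = rownames(values),
                         feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("omics matrix needs at least one feature")
  if (!all(is.finite(values))) stop("omics matrix has non-finite entries")
  if (is.null(subject_id)) subject_id <- as.character(seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  rownames(values) <- NULL
  colnames(values) <- feature_names
  structure(values, subject_id = as.character(subject_id),
            class = c("omics_matrix", "matrix", "array"))
}

#' Read an omics matrix from a delimited file
#'
#' @inheritParams load_clinical
#' @return An [omics_matrix()].
#' @export
load_omics <- function(path, id_col = "subject_id", sep = NULL) {
  df <- read_delim_guess(path, sep)
  if (!id_col %in% names(df))
    stop("subject id column '", id_col, "' not found in ", path)
  ids <- as.character(df[[id_col]])
  df[[id_col]] <- NULL
  if (anyNA(df)) stop("missing values in omics matrix")
  omics_matrix(as.matrix(df), subject_id = ids)
}

#' Write a clinical table or omics matrix to delimited text
#'
#' Numeric values are serialized with 17 significant digits so that a write
#' followed by a read reproduces every double bit-exactly.
#'
#' @param x a [clinical_table()] or [omics_matrix()].
#' @param path output file; `.tsv`/`.txt` extension selects tab separation.
#' @param id_col name for the subject-id column.
#' @export
write_subject_table <- function(x, path, id_col = "subject_id") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE,
                      check.names = FALSE)
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  out <- cbind(stats::setNames(data.frame(attr(x, "subject_id"),
                                          stringsAsFactors = FALSE), id_col),
               df)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_guess <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Align an omics matrix to a clinical table by subject id
#'
#' Joins on the subject identifier, never on row order; an id present in one
#' input but not the other is an error, not a silent drop.
#'
#' @param clinical a [clinical_table()].
#' @param omics an [omics_matrix()].
#' @return `omics` with rows reordered to the clinical table's subject order.
#' @export
align_subjects <- function(clinical, omics) {
  cid <- attr(clinical, "subject_id")
  oid <- attr(omics, "subject_id")
  if (!setequal(cid, oid))
    stop("subject ids of clinical table and omics matrix do not match: ",
         length(setdiff(cid, oid)), " clinical-only, ",
         length(setdiff(oid, cid)), " omics-only")
  idx <- match(cid, oid)
  omics_matrix(unclass(omics)[idx, , drop = FALSE], subject_id = cid,
               feature_names = colnames(omics))
}

#' Construct an undirected pathway graph
#'
#' @param nodes character vector of member feature names.
#' @param edges two-column character matrix/data.frame of undirected edges;
#'   endpoints must be members (self-loops are rejected).
#' @param name pathway label.
#' @return A `pathway_graph` list with elements `name`, `nodes`, `edges`.
#' @export
pathway_graph <- function(nodes, edges = NULL, name = "pathway") {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    bad <- !(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    if (any(bad)) stop("edge endpoints outside the node set")
  }
  colnames(edges) <- c("from", "to")
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Load pathway graphs from GMT membership plus an edge list
#'
#' The GMT dialect is the standard one: pathway name, description, then
#' tab-separated member features. Edges come from a 3-column TSV
#' (node_a, node_b, pathway); edges whose endpoints are not members of the
#' named pathway are dropped with a warning. Pathways below `min_size`
#' members are discarded (default 10, the usual smallest size at which a
#' pathway-level kernel test is sensible).
#'
#' @param gmt_path GMT file path.
#' @param edge_path optional edge-list TSV path (columns node_a, node_b,
#'   pathway; no header required).
#' @param min_size minimum member count for a pathway to be kept.
#' @return Named list of [pathway_graph()] objects.
#' @export
load_pathways <- function(gmt_path, edge_path = NULL, min_size = 10) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  edges_all <- NULL
  if (!is.null(edge_path) && file.exists(edge_path) &&
      file.size(edge_path) > 0) {
    edges_all <- utils::read.table(edge_path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE)
    if (ncol(edges_all) < 3L) stop("edge list must have 3 columns")
    names(edges_all)[1:3] <- c("from", "to", "pathway")
  }
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 40))
    nm <- parts[1]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) < min_size) next
    ed <- NULL
    if (!is.null(edges_all)) {
      sub <- edges_all[edges_all$pathway == nm, , drop = FALSE]
      if (nrow(sub)) {
        keep <- sub$from %in% members & sub$to %in% members
        if (any(!keep))
          warning(sum(!keep), " edge(s) in pathway '", nm,
                  "' reference non-member nodes; dropped")
        ed <- as.matrix(sub[keep, c("from", "to"), drop = FALSE])
      }
    }
    out[[nm]] <- pathway_graph(members, ed, name = nm)
  }
  out
}

#' Log-ratio transform of a proportion
#'
#' `log(x / (1 - x))` for `x` in (0, 1); used e.g. to normalize the
#' FEV1/FVC ratio before it serves as a continuous outcome.
#'
#' @param x numeric vector with entries strictly inside (0, 1).
#' @return `log(x / (1 - x))`.
#' @export
logit_ratio_transform <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("logit_ratio_transform requires 0 < x < 1")
  log(x / (1 - x))
}

#' Construct an outcome vector
#'
#' @param values numeric vector (0/1 for `family = "binomial"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return An `outcome` object.
#' @export
outcome <- function(values, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values in outcome")
  if (family == "binomial" && !all(values %in% c(0, 1)))
    stop("binomial outcome must be coded 0/1")
  structure(list(values = values, family = family), class = "outcome")
}
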