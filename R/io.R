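#' Read a gene expression matrix from TSV or GCT
#'
#' Reads a genes x samples expression matrix. The first column holds gene
#' identifiers, remaining columns hold per-sample values. GCT files carry the
#' standard two-line header (`#1.2` then declared dimensions) and a
#' Description column that is dropped. Duplicate gene rows are collapsed by
#' the arithmetic mean of their observed values; empty cells become `NA` and
#' can later be filled by [impute_row_mean()].
#'
#' Gene identifiers are treated as opaque case-sensitive strings; matching
#' against networks and gene sets is exact string equality.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gct"`.
#' @return A numeric matrix with gene rownames and sample colnames, in file
#'   order (first occurrence for collapsed duplicates).
#' @seealso [write_expression()], [read_network_sif()], [read_gmt()]
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !grepl("^#1\\.", lines[1L])) {
      stop("malformed GCT header in ", path, call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]][1:2]))
    if (anyNA(dims)) stop("malformed GCT dimension line in ", path, call. = FALSE)
    df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                     header = TRUE, sep = "\t", check.names = FALSE,
                     na.strings = c("NA", ""), stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
      stop("GCT declared dimensions (", dims[1L], " x ", dims[2L],
           ") disagree with body (", nrow(df), " x ", ncol(df) - 2L, ")",
           call. = FALSE)
    }
    gene_ids <- as.character(df[[1L]])
    df <- df[, -(1:2), drop = FALSE]
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     na.strings = c("NA", ""), stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression file has no sample columns: ", path,
                            call. = FALSE)
    gene_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    chr <- m
    suppressWarnings(storage.mode(m) <- "double")
    bad <- !is.na(chr) & chr != "" & is.na(m)
    if (any(bad)) {
      stop("non-numeric expression values, e.g. '", chr[which(bad)[1L]], "'",
           call. = FALSE)
    }
  }
  rownames(m) <- gene_ids
  if (anyDuplicated(gene_ids)) m <- collapse_duplicate_rows(m, gene_ids)
  m
}

# mean-collapse duplicate gene rows, NA-aware, first-occurrence order
collapse_duplicate_rows <- function(m, gene_ids) {
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  sums <- rowsum(m0, group = gene_ids, reorder = FALSE)
  cnts <- rowsum(obs + 0, group = gene_ids, reorder = FALSE)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Write an expression-like matrix as TSV
#'
#' Inverse of [read_expression()] for the TSV dialect; missing values are
#' written as empty cells.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Header of the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read binary phenotype labels
#'
#' Two-column TSV with a header: sample identifier and label. Labels may be
#' `0`/`1` or the strings `normal`/`tumor` (case-insensitive).
#'
#' @param path Path to the file.
#' @return Named integer vector (0 = normal, 1 = tumor), names = sample ids.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs sample and label columns", call. = FALSE)
  lab <- df[[2L]]
  if (is.character(lab)) {
    low <- tolower(lab)
    if (!all(low %in% c("normal", "tumor"))) {
      stop("labels must be 0/1 or normal/tumor; got '",
           lab[which(!low %in% c("normal", "tumor"))[1L]], "'", call. = FALSE)
    }
    lab <- ifelse(low == "tumor", 1L, 0L)
  }
  align_labels(lab, as.character(df[[1L]]))
}

#' @rdname read_labels
#' @param labels Named 0/1 integer vector.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels), label = as.integer(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a directed pathway network
#'
#' A directed gene-gene graph: each node is a gene and each edge states that
#' the source gene acts on the target gene. The entropy edge-weighted
#' transition matrix is attached later by [build_entropy_transition()].
#'
#' @param name Network name (e.g. `"KEGG"`, `"PID"`).
#' @param edges Two-column character matrix or data frame (source, target).
#' @param nodes Optional node universe; defaults to the sorted union of edge
#'   endpoints.
#' @return An object of class `pathway_network` with fields `name`, `nodes`,
#'   `edges` and `transition` (`NULL` until built).
#' @export
pathway_network <- function(name, edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(0), ncol = 2L)
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("source", "target")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges in network '", name, "'",
                               call. = FALSE)
  if (is.null(nodes)) {
    nodes <- sort_c(unique(c(edges[, 1L], edges[, 2L])))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
    miss <- setdiff(unique(c(edges)), nodes)
    if (length(miss)) stop("edge endpoints missing from nodes: ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
  }
  structure(list(name = name, nodes = nodes, edges = edges,
                 transition = NULL),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Directed pathway network '", x$name, "': ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges",
      if (!is.null(x$transition)) " (transition built)", "\n", sep = "")
  invisible(x)
}

#' Read a directed network from a SIF edge list
#'
#' Each non-blank line is `source<TAB>relation<TAB>target`. The relation
#' token is ignored for topology: the direction of interaction is assumed
#' already encoded as source to target. Duplicate edge lines are
#' deduplicated; nodes are the sorted union of endpoints.
#'
#' @param path Path to the SIF file.
#' @param name Network name.
#' @return A [pathway_network()].
#' @export
read_network_sif <- function(path, name) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(keep)[which(nf != 3L)[1L]]
    stop("malformed SIF line ", bad, " in ", path,
         " (expected 3 tab-separated fields, got ", nf[which(nf != 3L)[1L]],
         ")", call. = FALSE)
  }
  src <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 3L)
  dup <- duplicated(paste(src, tgt, sep = "\r"))
  pathway_network(name, cbind(src[!dup], tgt[!dup]))
}

#' @rdname read_network_sif
#' @param net A `pathway_network`.
#' @param relation Relation token written in the middle column.
#' @export
write_sif <- function(net, path, relation = "interacts") {
  writeLines(paste(net$edges[, 1L], relation, net$edges[, 2L], sep = "\t"),
             path)
  invisible(path)
}

#' Construct a pathway collection
#'
#' Named gene sets with an optional source-network tag per pathway.
#'
#' @param members Named list of character vectors (pathway id -> member
#'   genes); sets are deduplicated and must be non-empty.
#' @param source Source network name, length 1 or one per pathway.
#' @param descriptions Optional per-pathway description strings.
#' @return An object of class `pathway_collection` with fields `pathway_ids`,
#'   `members`, `source`, `descriptions`.
#' @export
pathway_collection <- function(members, source = NA_character_,
                               descriptions = NULL) {
  ids <- names(members)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("pathway ids must be unique and named", call. = FALSE)
  }
  members <- lapply(members, function(g) unique(as.character(g)))
  if (any(lengths(members) == 0L)) {
    stop("empty pathway member set: ",
         ids[which(lengths(members) == 0L)[1L]], call. = FALSE)
  }
  source <- rep_len(as.character(source), length(ids))
  names(source) <- ids
  if (is.null(descriptions)) descriptions <- rep_len(NA_character_, length(ids))
  names(descriptions) <- ids
  structure(list(pathway_ids = ids, members = members, source = source,
                 descriptions = descriptions),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("Pathway collection: ", length(x$pathway_ids), " pathways, sizes ",
      min(lengths(x$members)), "-", max(lengths(x$members)), "\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is `pathway_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Repeated genes within a line count once; a duplicated pathway id is an
#' error.
#'
#' @param path Path to the GMT file.
#' @param source Source network name recorded for every pathway.
#' @return A [pathway_collection()] in file order.
#' @export
read_gmt <- function(path, source = NA_character_) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed GMT line ", keep[which(nf < 3L)[1L]], " in ", path,
         " (need id, description and at least one gene)", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- ids
  pathway_collection(members, source = source,
                     descriptions = vapply(fields, `[[`, "", 2L))
}

#' @rdname read_gmt
#' @param pc A `pathway_collection`.
#' @export
write_gmt <- function(pc, path) {
  desc <- ifelse(is.na(pc$descriptions), "na", pc$descriptions)
  lines <- vapply(seq_along(pc$pathway_ids), function(i) {
    paste(c(pc$pathway_ids[i], desc[i], pc$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
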