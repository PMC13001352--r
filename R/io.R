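#' Read / write feature-by-sample matrices as TSV
#'
#' The first column holds feature ids; remaining columns are samples.
#' Missing cells are written as `NA`.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read / write a sample design table
#'
#' @param design Design data.frame (see [validate_design()]).
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
  d
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `peak_id`.
#' @param path File path.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "peak_id")
  df
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member ids. Directional PTM
#' signature members are encoded as `"id;u"` / `"id;d"`; `read_gmt` keeps the
#' suffix in place so [parse_directional_set()] can resolve it.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Split a directional set into member ids and direction tags
#'
#' @param members Character vector, entries either `"id"` or `"id;u"`/`"id;d"`.
#' @return data.frame with columns `id` and `direction` (`"u"` when untagged).
#' @export
parse_directional_set <- function(members) {
  has_tag <- grepl(";[ud]$", members)
  id <- ifelse(has_tag, sub(";[ud]$", "", members), members)
  direction <- ifelse(has_tag, sub("^.*;", "", members), "u")
  data.frame(id = id, direction = direction, stringsAsFactors = FALSE)
}

#' Read / write bismark-style CpG coverage tables
#'
#' Long format: `chrom`, `pos` (1-based), `sample_id`, `methylated`, `total`.
#'
#' @param cov Coverage data.frame.
#' @param path File path.
#' @export
write_cpg_coverage <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_coverage
#' @export
read_cpg_coverage <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to an output directory
#'
#' Serializes per-ome matrices as TSV, the design as TSV, peaks as BED, gene
#' annotation as a GTF-like TSV, pathways as GMT, and the planted truth as
#' JSON. All files are plain text.
#'
#' @param bundle A `SyntheticBundle` from [simulate_omics()].
#' @param outdir Output directory (created if absent).
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (ome in names(bundle$omics)) {
    write_matrix_tsv(bundle$omics[[ome]]$values,
                     file.path(outdir, paste0(ome, ".tsv")))
  }
  write_design_tsv(bundle$design, file.path(outdir, "design.tsv"))
  tr <- bundle$truth
  write_bed(tr$peaks, file.path(outdir, "peaks.bed"))
  utils::write.table(tr$genes, file.path(outdir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(tr$pathways, file.path(outdir, "pathways.gmt"))
  truth_json <- list(
    perturbed_features = tr$perturbed_features,
    regulatory_edges = tr$regulatory_edges,
    peak_gene_links = tr$peak_gene_links,
    tf_genes = tr$tf_genes
  )
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(outdir)
}

#' Write a network edge table as TSV and GraphML
#'
#' @param edges Edge data.frame with at least `regulator`, `target`, `weight`.
#' @param path Base path; `.tsv` is written, and `.graphml` when
#'   `graphml = TRUE`.
#' @param graphml Also write GraphML via igraph.
#' @export
write_network <- function(edges, path, graphml = FALSE) {
  utils::write.table(edges, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (graphml) {
    g <- igraph::graph_from_data_frame(
      edges[, c("regulator", "target",
                setdiff(names(edges), c("regulator", "target")))],
      directed = TRUE)
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  }
  invisible(path)
}
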