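#' Read and write the tab-separated exchange tables
#'
#' All tabular artefacts are exchanged as UTF-8, header-row, tab-separated
#' values with `.` as the decimal mark. `write_tsv_sorted()` writes rows in
#' the order given (writers sort before calling it, so output is
#' deterministic); `read_tsv_quiet()` reads without column-spec chatter.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `write_tsv_sorted()` the input invisibly; `read_tsv_quiet()` a
#'   tibble.
#' @keywords internal
#' @noRd
write_tsv_sorted <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read an expression dataset (matrix + metadata) from TSV files
#'
#' Loads a feature-by-sample expression table and its sample metadata,
#' enforcing the dataset invariants: unique feature and sample ids, numeric
#' finite values, metadata covering every sample, and (for paired designs)
#' exactly one tumour and one normal sample per subject. When a probe map
#' is supplied, probes are collapsed to features by keeping the probe with
#' the highest mean expression per feature.
#'
#' @param matrix_path TSV with a `feature_id` column and one numeric column
#'   per sample.
#' @param metadata_path TSV with `sample_id`, `subject_id`, `condition`.
#' @param design `"paired"` or `"group"`.
#' @param probe_map Optional tibble or TSV path with `probe_id`,
#'   `feature_id` columns mapping matrix rows to features.
#' @return List with `expr` (tibble), `metadata` (tibble) and `design`.
#' @export
read_expression_bundle <- function(matrix_path, metadata_path,
                                   design = c("paired", "group"),
                                   probe_map = NULL) {
  design <- match.arg(design)
  expr <- read_tsv_quiet(matrix_path)
  metadata <- read_tsv_quiet(metadata_path,
                             col_types = readr::cols(.default = "c"))
  if (!is.null(probe_map)) {
    if (is.character(probe_map)) probe_map <- read_tsv_quiet(probe_map)
    if (!all(c("probe_id", "feature_id") %in% names(probe_map))) {
      stop_input("probe map must carry probe_id and feature_id columns")
    }
    expr <- expr |>
      rename(probe_id = "feature_id") |>
      inner_join(probe_map, by = "probe_id")
    sample_cols <- setdiff(names(expr), c("probe_id", "feature_id"))
    expr <- expr |>
      mutate(.mean = rowMeans(dplyr::pick(dplyr::all_of(sample_cols)))) |>
      group_by(.data$feature_id) |>
      arrange(dplyr::desc(.data$.mean), .by_group = TRUE) |>
      dplyr::slice(1L) |>
      ungroup() |>
      select("feature_id", dplyr::all_of(sample_cols))
  }
  m <- expr_to_matrix(expr)                     # enforces invariants
  check_metadata(metadata, colnames(m), design) # enforces pairing
  list(expr = expr, metadata = metadata, design = design)
}

#' Write a synthetic study bundle to a directory
#'
#' Serialises a [simulate_study()] bundle as plain-text artefacts: one
#' expression TSV per (dataset, molecule kind), one metadata TSV per
#' dataset, the evidence TSV, miRNA and lncRNA FASTA files, and the ground
#' truth as JSON. All writers emit deterministic, sorted output.
#'
#' @param bundle A `cerna_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "cerna_bundle")) {
    stop_input("`bundle` must be a cerna_bundle from simulate_study()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(bundle$datasets)) {
    ds <- bundle$datasets[[id]]
    for (kind in names(ds$expr)) {
      p <- file.path(dir, sprintf("%s_%s_expr.tsv", id, kind))
      write_tsv_sorted(arrange(ds$expr[[kind]], .data$feature_id), p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s_metadata.tsv", id))
    write_tsv_sorted(ds$metadata, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "evidence.tsv")
  write_tsv_sorted(bundle$evidence, p)
  paths <- c(paths, p)
  for (kind in c("mirna", "lncrna")) {
    p <- file.path(dir, sprintf("%s.fasta", kind))
    write_fasta(bundle$sequences[[kind]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(bundle$truth, p, dataframe = "rows", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read and write FASTA sequence tables
#'
#' Thin wrappers mapping between the package's sequence tibbles (`id`,
#' `seq`) and FASTA files, using Biostrings when available and a plain
#' line-based fallback otherwise.
#'
#' @param sequences Tibble with `id` and `seq`.
#' @param path FASTA file path.
#' @return `read_fasta()` a sequence tibble; `write_fasta()` the path,
#'   invisibly.
#' @export
write_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", sequences$id), sequences$seq))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("FASTA file not found: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    return(tibble(id = names(ss), seq = unname(as.character(ss))))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_input("no FASTA records found")
  id <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  tibble(id = sub("\\s.*$", "", id), seq = unname(seqs))
}

#' Write a ceRNA network as SIF plus node attributes
#'
#' Writes `network.sif` (`source<TAB>edge_kind<TAB>target`, sorted) and
#' `node_attributes.tsv` (`id`, `node_kind`, `direction`, `degree`).
#'
#' @param network A `cerna_network` from [build_network()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two written paths.
#' @export
write_network <- function(network, dir) {
  if (!inherits(network, "cerna_network")) {
    stop_input("`network` must be a cerna_network from build_network()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif_path <- file.path(dir, "network.sif")
  edges <- arrange(network$edges, .data$source, .data$edge_kind, .data$target)
  writeLines(sprintf("%s\t%s\t%s", edges$source, edges$edge_kind,
                     edges$target), sif_path)
  attr_path <- file.path(dir, "node_attributes.tsv")
  write_tsv_sorted(arrange(network$nodes, .data$id), attr_path)
  invisible(c(sif = sif_path, attributes = attr_path))
}

#' @rdname write_network
#' @param sif_path,attr_path Paths written by `write_network()`.
#' @return `read_network()` a `cerna_network`.
#' @export
read_network <- function(sif_path, attr_path) {
  if (!file.exists(sif_path)) stop_input(sprintf("SIF file not found: %s", sif_path))
  lines <- readLines(sif_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  edges <- if (length(lines) == 0) {
    tibble(source = character(0), target = character(0),
           edge_kind = character(0))
  } else {
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    tibble(source = f[, 1], edge_kind = f[, 2], target = f[, 3])
  }
  nodes <- read_tsv_quiet(attr_path)
  structure(list(nodes = nodes,
                 edges = select(edges, "source", "target", "edge_kind") |>
                   arrange(.data$edge_kind, .data$source, .data$target),
                 degree_edges = "all"),
            class = "cerna_network")
}
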