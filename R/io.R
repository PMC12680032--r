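#' Read a single-cell SMR event table
#'
#' Reads one row per measured cell from a headered delimited text file as
#' written by SMR acquisition software. Mandatory columns are `cell_id`,
#' `sample_id` and `buoyant_mass` (pg); optional columns are `condition`
#' (one of `"reference"`, `"vehicle"`, `"drug"`, `"untyped"`), `stiffness`
#' (arbitrary units), `volume` (um^3) and `viable` (logical).
#'
#' @param path Path to a CSV or TSV file.
#' @param delim Field delimiter. `NULL` (default) picks `"\t"` for files
#'   ending in `.tsv`/`.txt` and `","` otherwise.
#' @return A data frame of class `smr_events` with one validated row per
#'   cell. Comment lines starting with `#` are skipped.
#' @seealso [write_smr_events()], [pair_events_with_matrix()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cell_id,sample_id,buoyant_mass",
#'              "c1,s1,60.1", "c2,s1,72.4"), tf)
#' read_smr_events(tf)
read_smr_events <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop("SMR event file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.delim(path, sep = delim, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  as_smr_events(df)
}

#' Validate a data frame of SMR events
#'
#' @param df A data frame with at least `cell_id`, `sample_id`,
#'   `buoyant_mass`.
#' @return The validated `smr_events` data frame, with `condition`
#'   defaulted to `"untyped"` when absent.
#' @export
as_smr_events <- function(df) {
  mandatory <- c("cell_id", "sample_id", "buoyant_mass")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("SMR event table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$cell_id <- as.character(df$cell_id)
  df$sample_id <- as.character(df$sample_id)
  mass <- suppressWarnings(as.numeric(df$buoyant_mass))
  bad_parse <- which(is.na(mass) & !is.na(df$buoyant_mass) &
                       df$buoyant_mass != "")
  if (length(bad_parse) > 0) {
    stop("Unparseable buoyant_mass value(s) at row(s): ",
         paste(bad_parse, collapse = ", "), call. = FALSE)
  }
  df$buoyant_mass <- mass
  bad_mass <- which(!is.finite(df$buoyant_mass) | df$buoyant_mass <= 0)
  if (length(bad_mass) > 0) {
    stop("buoyant_mass must be finite and positive; offending row(s): ",
         paste(bad_mass, collapse = ", "), call. = FALSE)
  }
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup) > 0) {
    stop("Duplicate cell_id in SMR event table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!"condition" %in% names(df)) {
    df$condition <- "untyped"
  }
  bad_cond <- setdiff(unique(df$condition),
                      c("reference", "vehicle", "drug", "untyped"))
  if (length(bad_cond) > 0) {
    stop("Unknown condition value(s): ", paste(bad_cond, collapse = ", "),
         "; expected reference/vehicle/drug/untyped", call. = FALSE)
  }
  if ("volume" %in% names(df)) {
    df$volume <- suppressWarnings(as.numeric(df$volume))
    bad_vol <- which(!is.na(df$volume) & df$volume <= 0)
    if (length(bad_vol) > 0) {
      stop("volume must be positive where present; offending row(s): ",
           paste(bad_vol, collapse = ", "), call. = FALSE)
    }
  }
  if ("stiffness" %in% names(df)) {
    df$stiffness <- suppressWarnings(as.numeric(df$stiffness))
  }
  if ("viable" %in% names(df)) {
    df$viable <- as.logical(df$viable)
  }
  class(df) <- c("smr_events", "data.frame")
  df
}

#' Write an SMR event table
#'
#' Numeric fields are formatted with 15 significant digits so that a
#' write/read round trip preserves values bit-exactly.
#'
#' @param events An `smr_events` data frame.
#' @param path Output path; delimiter chosen as in [read_smr_events()].
#' @param header Optional character vector of `#`-prefixed metadata lines
#'   written before the column header.
#' @return `path`, invisibly.
#' @export
write_smr_events <- function(events, path, header = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- as.data.frame(events)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("#", sub("^#", "", header)), con)
  }
  write.table(out, con, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-by-cell count matrix container
#'
#' @param counts A non-negative integer matrix (base or `Matrix` sparse),
#'   genes in rows, cells in columns, with dimnames set.
#' @param mito_genes Character vector of mitochondrial gene symbols
#'   (must be a subset of the row names).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (a `dgCMatrix`) and `mito_genes`.
#' @export
count_matrix <- function(counts, mito_genes = character(0)) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and cell column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and cell labels must be duplicate-free", call. = FALSE)
  }
  m <- as(as(as(Matrix::Matrix(counts), "dMatrix"), "generalMatrix"),
          "CsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(mito_genes, rownames(m))
  if (length(bad) > 0) {
    stop("mito_genes not present in matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = m, mito_genes = mito_genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), length(x$mito_genes)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene and cell labels of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of labels.
#' @export
genes <- function(x) rownames(x$counts)

#' @rdname genes
#' @export
cells <- function(x) colnames(x$counts)

#' Read a gene-by-cell count matrix
#'
#' Supports MatrixMarket triplet files (1-based indices per the standard;
#' converted to R's internal representation at the boundary) with plain-text
#' gene and cell label sidecars, and dense TSV with genes in rows (first
#' column holding gene symbols) and one column per cell.
#'
#' @param path Path to the `.mtx` or dense TSV file.
#' @param format `"mtx"` or `"dense"`; default guesses from the extension.
#' @param genes_path,cells_path Label sidecars for `"mtx"` (one label per
#'   line); default `<path minus .mtx>.genes.txt` / `.cells.txt`.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path,
                              format = c("guess", "mtx", "dense"),
                              genes_path = NULL, cells_path = NULL,
                              mito_prefix = "MT-") {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(stem, ".cells.txt")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) {
        stop("label sidecar not found: ", p, call. = FALSE)
      }
    }
    m <- as(as(Matrix::readMM(path), "generalMatrix"), "CsparseMatrix")
    g <- readLines(genes_path)
    cl <- readLines(cells_path)
    if (nrow(m) != length(g) || ncol(m) != length(cl)) {
      stop(sprintf(
        "dimension mismatch: matrix is %d x %d but sidecars give %d genes, %d cells",
        nrow(m), ncol(m), length(g), length(cl)), call. = FALSE)
    }
    dimnames(m) <- list(g, cl)
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE, stringsAsFactors = FALSE)
    g <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- g
  }
  count_matrix(m, mito_genes = grep(paste0("^", mito_prefix), rownames(m),
                                    value = TRUE))
}

#' Write a count matrix
#'
#' @param x A [count_matrix()].
#' @param path Output `.mtx` (with `.genes.txt` / `.cells.txt` sidecars) or
#'   dense TSV path.
#' @param format `"mtx"` or `"dense"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("guess", "mtx", "dense")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    Matrix::writeMM(x$counts, path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(x$counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(x$counts), paste0(stem, ".cells.txt"))
  } else {
    df <- data.frame(gene = rownames(x$counts),
                     as.matrix(x$counts), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Pair SMR events with an expression matrix by cell identifier
#'
#' Inner join on `cell_id`: cells present on only one side are dropped and
#' reported, because the linked-platform workflow routinely measures cells
#' whose libraries later fail QC or prep. Zero overlap is an error.
#'
#' @param events An `smr_events` table.
#' @param matrix A [count_matrix()].
#' @param model_map Named character vector mapping `cell_id` to a model
#'   label (e.g. PDX model). Default uses `sample_id` from `events`.
#' @param tissue_map Optional named character vector mapping `cell_id` to a
#'   tissue label.
#' @return An object of class `paired_dataset`: list with `events`,
#'   `matrix`, `model` (per retained cell), `tissue` (or `NULL`) and
#'   `join_report` (counts and identities of dropped cells on each side).
#' @export
pair_events_with_matrix <- function(events, matrix, model_map = NULL,
                                    tissue_map = NULL) {
  events <- as_smr_events(as.data.frame(events))
  common <- intersect(events$cell_id, cells(matrix))
  if (length(common) == 0) {
    stop("no overlapping cell_id between events and count matrix",
         call. = FALSE)
  }
  common <- sort(common)
  dropped_events <- sort(setdiff(events$cell_id, common))
  dropped_cells <- sort(setdiff(cells(matrix), common))
  ev <- events[match(common, events$cell_id), , drop = FALSE]
  rownames(ev) <- NULL
  cm <- count_matrix(matrix$counts[, common, drop = FALSE],
                     mito_genes = matrix$mito_genes)
  model <- if (is.null(model_map)) {
    setNames(ev$sample_id, ev$cell_id)
  } else {
    mm <- model_map[common]
    if (anyNA(mm)) {
      stop("model_map does not cover retained cell(s): ",
           paste(common[is.na(mm)], collapse = ", "), call. = FALSE)
    }
    setNames(as.character(mm), common)
  }
  tissue <- if (is.null(tissue_map)) NULL else {
    setNames(as.character(tissue_map[common]), common)
  }
  structure(list(
    events = ev, matrix = cm, model = model, tissue = tissue,
    join_report = list(n_matched = length(common),
                       dropped_events = dropped_events,
                       dropped_matrix_cells = dropped_cells)),
    class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "paired_dataset: %d linked cells, %d genes (%d event-only, %d matrix-only dropped)\n",
    x$join_report$n_matched, nrow(x$matrix$counts),
    length(x$join_report$dropped_events),
    length(x$join_report$dropped_matrix_cells)))
  invisible(x)
}
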