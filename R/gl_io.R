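#' Genotype-likelihood dataset container
#'
#' The universal input of the pipeline: an ordered marker table plus a
#' sites x individuals x 3 array of genotype likelihoods (probability of the
#' read data given 0, 1 or 2 copies of the minor allele). Triplets are
#' normalized to sum to 1; an exactly flat triplet encodes missingness
#' (depth 0). Positions must be strictly increasing within chromosomes and
#' genomic coordinates are 1-based inclusive throughout the package.
#'
#' @param markers data.frame with columns `chrom`, `pos`, `major`, `minor`.
#' @param gl numeric array, `nrow(markers)` x n individuals x 3, non-negative.
#' @param ids character vector of unique individual ids.
#' @return an object of class `gl_dataset`.
#' @export
gl_dataset <- function(markers, gl, ids) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "major", "minor") %in% names(markers)),
            length(dim(gl)) == 3L, dim(gl)[3] == 3L,
            dim(gl)[1] == nrow(markers), dim(gl)[2] == length(ids))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  if (!identical(ord, seq_len(nrow(markers))))
    stop("markers must be sorted by chromosome and position")
  for (chr in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == chr]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  if (any(gl < 0, na.rm = TRUE)) stop("genotype likelihoods must be non-negative")
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("each likelihood triplet must have a positive finite sum")
  for (g in 1:3) gl[, , g] <- gl[, , g] / tot
  rownames(markers) <- NULL
  structure(list(markers = markers, gl = gl, ids = as.character(ids)),
            class = "gl_dataset")
}

#' @export
print.gl_dataset <- function(x, ...) {
  cat(sprintf("gl_dataset: %d markers x %d individuals on %d chromosome(s)\n",
              nrow(x$markers), length(x$ids),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' Number of markers / individuals
#' @param ds a [gl_dataset()].
#' @return integer count.
#' @export
n_markers <- function(ds) nrow(ds$markers)

#' @rdname n_markers
#' @export
n_individuals <- function(ds) length(ds$ids)

# genotype-likelihood slice as a sites x individuals matrix, robust to
# single-site or single-individual datasets (where `[ , , k]` drops dims)
.gl_slice <- function(gl, k) {
  m <- gl[, , k]
  if (is.null(dim(m))) dim(m) <- dim(gl)[1:2]
  m
}

#' Missingness mask of a dataset
#'
#' A site x individual entry is missing when its normalized triplet is flat
#' (all three values equal within 1e-9), the behaviour of depth-0 sites in
#' genotype-likelihood pipelines.
#'
#' @param ds a [gl_dataset()].
#' @return logical matrix, sites x individuals.
#' @export
gl_missing <- function(ds) {
  mx <- pmax(.gl_slice(ds$gl, 1), .gl_slice(ds$gl, 2), .gl_slice(ds$gl, 3))
  mn <- pmin(.gl_slice(ds$gl, 1), .gl_slice(ds$gl, 2), .gl_slice(ds$gl, 3))
  m <- (mx - mn) < 1e-9
  dim(m) <- dim(ds$gl)[1:2]
  m
}

#' Subset a dataset by marker rows and/or individuals
#' @param ds a [gl_dataset()].
#' @param sites integer or logical index over markers (optional).
#' @param individuals integer, logical or character index over ids (optional).
#' @return a [gl_dataset()].
#' @export
gl_subset <- function(ds, sites = NULL, individuals = NULL) {
  if (is.null(sites)) sites <- seq_len(n_markers(ds))
  if (is.null(individuals)) individuals <- seq_along(ds$ids)
  if (is.character(individuals)) individuals <- match(individuals, ds$ids)
  gl_dataset(ds$markers[sites, , drop = FALSE],
             ds$gl[sites, individuals, , drop = FALSE],
             ds$ids[individuals])
}

#' Read a Beagle genotype-likelihood file
#'
#' Expects the ANGSD interchange layout: header `marker allele1 allele2`
#' followed by three likelihood columns per individual; marker names are
#' `chrom_pos`, split on the last underscore so chromosome names may contain
#' underscores. Any positive scaling of the triplets is accepted (dialects
#' differ); triplets are renormalized on read and exactly-flat triplets are
#' treated as missing.
#'
#' @param path file path.
#' @return a [gl_dataset()]; individual ids are taken from the header when
#'   informative, otherwise `ind1..indN`.
#' @export
read_beagle <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 6L || (ncol(dt) - 3L) %% 3L != 0L)
    stop("malformed Beagle file: expected 3 + 3k columns, got ", ncol(dt))
  marker <- dt[[1L]]
  dup <- anyDuplicated(marker)
  if (dup) stop("duplicated marker at line ", dup + 1L, ": ", marker[dup])
  lik <- as.matrix(dt[, -(1:3)])
  if (!is.numeric(lik)) {
    bad <- which(!apply(dt[, -(1:3)], 2, is.numeric))[1L]
    col <- suppressWarnings(as.numeric(dt[[bad + 3L]]))
    stop("non-numeric likelihood at line ",
         which(is.na(col))[1L] + 1L, ", column ", bad + 3L)
  }
  n_ind <- ncol(lik) / 3L
  chrom <- sub("_[^_]*$", "", marker)
  pos <- suppressWarnings(as.integer(sub(".*_", "", marker)))
  if (anyNA(pos)) stop("marker names must be chrom_pos; offending line ",
                       which(is.na(pos))[1L] + 1L)
  hdr <- names(dt)[-(1:3)]
  ids <- unique(sub("(\\.[0-9]+)?$", "", make.names(hdr)))
  if (length(ids) != n_ind) ids <- paste0("ind", seq_len(n_ind))
  gl <- array(NA_real_, c(nrow(dt), n_ind, 3L))
  for (g in 1:3) gl[, , g] <- lik[, seq(g, ncol(lik), by = 3L)]
  major <- toupper(dt[[2L]]); minor <- toupper(dt[[3L]])
  num <- suppressWarnings(as.integer(major))
  if (!anyNA(num)) {  # ANGSD numeric allele coding 0..3
    code <- c("A", "C", "G", "T")
    major <- code[num + 1L]
    minor <- code[as.integer(minor) + 1L]
  }
  gl_dataset(data.frame(chrom = chrom, pos = pos, major = major,
                        minor = minor), gl, ids)
}

#' Write a Beagle genotype-likelihood file
#'
#' @param ds a [gl_dataset()].
#' @param path output path.
#' @param digits significant digits for likelihoods (at least 6).
#' @return `path`, invisibly.
#' @export
write_beagle <- function(ds, path, digits = 7) {
  stopifnot(digits >= 6)
  n_ind <- n_individuals(ds)
  out <- vector("list", 3L + 3L * n_ind)
  out[[1L]] <- paste(ds$markers$chrom, ds$markers$pos, sep = "_")
  out[[2L]] <- ds$markers$major
  out[[3L]] <- ds$markers$minor
  nm <- c("marker", "allele1", "allele2",
          paste0(rep(ds$ids, each = 3L), c("", ".1", ".2")))
  for (i in seq_len(n_ind)) for (g in 1:3)
    out[[3L + (i - 1L) * 3L + g]] <- signif(ds$gl[, i, g], digits)
  names(out) <- nm
  data.table::fwrite(data.table::as.data.table(out), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read / write genomic regions as BED3+
#'
#' Internal region coordinates are 1-based inclusive; BED files are 0-based
#' half-open, so `internal start = BED start + 1` and `internal end = BED
#' end`. Columns beyond the third (label, provenance, score) are preserved
#' when present.
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `label`, `provenance`, `score`.
#' @export
read_regions_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.numeric(dt[[2L]]) + 1,
                    end = as.numeric(dt[[3L]]))
  if (any(out$start > out$end))
    stop("BED start must be strictly less than end")
  extras <- c("label", "provenance", "score")
  for (k in seq_len(min(ncol(dt) - 3L, 3L))) out[[extras[k]]] <- dt[[3L + k]]
  out
}

#' @rdname read_regions_bed
#' @param regions data.frame of 1-based inclusive regions.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) stop("region start must be <= end")
  extras <- intersect(c("label", "provenance", "score"), names(regions))
  out <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE))
  for (k in extras) out[[k]] <- regions[[k]]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an Arc-ASCII habitat raster
#'
#' Cell values: 0 = water, 1 = land. Cell size is interpreted in km. Rows in
#' the file run north to south; the returned matrix keeps that order (row 1 =
#' top).
#'
#' @param path Arc-ASCII grid file.
#' @return object of class `raster_map`: list with `grid` (integer matrix),
#'   `xll`, `yll`, `cellsize`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("raster header missing ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster body does not match declared dimensions")
  grid <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
                 byrow = TRUE)
  if (!all(grid %in% c(0L, 1L))) stop("raster cells must be 0 (water) or 1 (land)")
  structure(list(grid = grid, xll = hdr$xllcorner %||% 0,
                 yll = hdr$yllcorner %||% 0, cellsize = hdr$cellsize),
            class = "raster_map")
}

#' Write an Arc-ASCII habitat raster
#' @param raster a `raster_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(raster$grid)),
               paste("nrows", nrow(raster$grid)),
               paste("xllcorner", raster$xll),
               paste("yllcorner", raster$yll),
               paste("cellsize", raster$cellsize)), con)
  apply(raster$grid, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps records of type `gene` (1-based inclusive coordinates); other
#' feature types are skipped with a single warning. The gene id is taken
#' from the `ID=` attribute, falling back to `Name=`.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 9L
  if (any(bad)) stop("malformed GFF record at line ", which(bad)[1L])
  type <- vapply(fields, `[[`, "", 3L)
  keep <- type == "gene"
  if (any(!keep))
    warning(sum(!keep), " non-gene GFF record(s) skipped")
  fields <- fields[keep]
  if (!length(fields))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character()))
  attr_id <- function(s) {
    m <- regmatches(s, regexec("(?:^|;)(?:ID|Name)=([^;]+)", s))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  out <- data.frame(
    gene_id = vapply(fields, function(f) attr_id(f[9L]), ""),
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 4L)),
    end = as.numeric(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L))
  if (any(is.na(out$start) | is.na(out$end) | out$end < out$start))
    stop("GFF gene with end < start or non-numeric coordinates")
  if (anyNA(out$gene_id)) stop("GFF gene record without ID/Name attribute")
  out
}

#' Read a gene-to-GO mapping table
#'
#' Two-column TSV (gene id, GO id); duplicate rows are de-duplicated. GO ids
#' must match `GO:` followed by 7 digits. The mapping is assumed to be
#' pre-propagated up the GO graph.
#'
#' @param path TSV file (no header, or header `gene_id`/`go_id`).
#' @return data.frame with columns `gene_id`, `go_id`, one row per pair.
#' @export
read_gene2go <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("gene2go needs two columns")
  out <- data.frame(gene_id = as.character(dt[[1L]]),
                    go_id = as.character(dt[[2L]]))
  if (identical(tolower(out$gene_id[1L]), "gene_id")) out <- out[-1L, ]
  if (!all(grepl("^GO:[0-9]{7}$", out$go_id)))
    stop("malformed GO id: ", out$go_id[!grepl("^GO:[0-9]{7}$", out$go_id)][1L])
  unique(out)
}

#' Read / write a per-site read-depth sidecar
#'
#' TSV with a `marker` column plus one integer column per individual,
#' aligned to the dataset marker order.
#'
#' @param path TSV file.
#' @return integer matrix (sites x individuals) with marker rownames.
#' @export
read_depth_sidecar <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1L])
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("depth sidecar contains non-integer entries")
  rownames(m) <- dt[[1L]]
  m
}

#' @rdname read_depth_sidecar
#' @param depth integer matrix, sites x individuals.
#' @param ds the matching [gl_dataset()] (for marker names and ids).
#' @export
write_depth_sidecar <- function(depth, ds, path) {
  out <- data.table::as.data.table(depth)
  names(out) <- ds$ids
  out <- cbind(data.table::data.table(
    marker = paste(ds$markers$chrom, ds$markers$pos, sep = "_")), out)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' TSV with at least `id` and `site` columns; optional `lat`, `lon`, `row`,
#' `col` (raster grid cell) and `group`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  out <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  if (!all(c("id", "site") %in% names(out)))
    stop("sample table needs `id` and `site` columns")
  if (anyDuplicated(out$id)) stop("sample ids must be unique")
  out
}

#' @rdname read_sample_table
#' @param samples data.frame with `id` and `site` columns.
#' @export
write_sample_table <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", quote = FALSE)
  invisible(path)
}
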