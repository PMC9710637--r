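#' Parse a location-annotated FASTA file
#'
#' Reads protein records from a FASTA file whose headers follow the DeepLoc
#' dialect: whitespace-separated accession, then `Class-Flag` where the flag
#' is one of `M` (membrane), `S` (soluble), `U` (unknown), then an optional
#' `test` token marking test-set membership. Example header:
#' `>P12345 Nucleus-S test`.
#'
#' @param path FASTA file path.
#' @param aliases alias table mapping class spellings to the canonical
#'   vocabulary, see [class_aliases()].
#' @return data.frame with columns `id`, `sequence`, `location`,
#'   `membrane_flag`, `split` — one row per FASTA entry.
#' @export
parse_location_fasta <- function(path, aliases = class_aliases()) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(seqs)
  toks <- strsplit(trimws(headers), "\\s+")
  parse_one <- function(tok, header) {
    if (length(tok) < 2L)
      stop("malformed header (need 'accession Class-Flag'): ", header, call. = FALSE)
    id <- tok[[1L]]
    lab <- tok[[2L]]
    m <- regmatches(lab, regexec("^(.*)-([MSU])$", lab))[[1L]]
    if (length(m) == 3L) {
      cls <- m[[2L]]; flag <- m[[3L]]
    } else {
      cls <- lab; flag <- NA_character_
    }
    split <- if (length(tok) >= 3L && tok[[3L]] == "test") "test" else "train"
    list(id = id, class_token = cls, flag = flag, split = split, header = header)
  }
  parsed <- Map(parse_one, toks, headers)
  ids <- vapply(parsed, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  loc <- resolve_class(
    vapply(parsed, `[[`, "", "class_token"),
    aliases = aliases,
    context = paste0("header '", headers, "'")
  )
  data.frame(
    id = ids,
    sequence = as.character(seqs),
    location = loc,
    membrane_flag = vapply(parsed, `[[`, "", "flag"),
    split = vapply(parsed, `[[`, "", "split"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Read a two-column TSV label file
#'
#' Alternative to annotated FASTA for datasets without sequences (e.g.
#' synthetic embeddings): `id <TAB> class`, optional third column `split`.
#' A header line `id<TAB>location...` is detected and skipped.
#'
#' @param path TSV path.
#' @param aliases see [class_aliases()].
#' @return data.frame with columns `id`, `location`, `split` (split defaults
#'   to `train` when absent).
#' @export
read_labels_tsv <- function(path, aliases = class_aliases()) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty label file: ", path, call. = FALSE)
  if (df[1L, 1L] %in% c("id", "accession")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("label TSV needs at least two columns (id, class)",
                          call. = FALSE)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id(s) in label file: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    id = ids,
    location = resolve_class(df[[2L]], aliases, context = paste0("id '", ids, "'")),
    split = if (ncol(df) >= 3L) df[[3L]] else "train",
    stringsAsFactors = FALSE
  )
  bad <- !out$split %in% c("train", "validation", "test")
  if (any(bad)) stop("invalid split value(s): ",
                     paste(unique(out$split[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Write a label TSV
#' @param records data.frame with `id`, `location` and optionally `split`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(records, path) {
  stopifnot(all(c("id", "location") %in% names(records)))
  cols <- c("id", "location", if ("split" %in% names(records)) "split")
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an embedding container
#'
#' Stores a keyed set of per-protein embedding matrices in a single container
#' file (RDS-backed). Matrices are stored in the `L x d_in` orientation
#' (residues x embedding width), the convention of per-protein embedding
#' dumps; [read_embeddings()] transposes back to the internal `d_in x L`
#' orientation used by the model.
#'
#' @param embeddings named list of numeric matrices, each `d_in x L` (model
#'   orientation).
#' @param path output file.
#' @param append if `TRUE` and `path` exists, add to it; colliding ids are an
#'   error.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, append = FALSE) {
  stopifnot(is.list(embeddings))
  if (length(embeddings) > 0L) {
    if (is.null(names(embeddings)) || any(!nzchar(names(embeddings))))
      stop("embeddings must be a named list keyed by accession", call. = FALSE)
    d_ins <- vapply(embeddings, nrow, 0L)
    if (length(unique(d_ins)) > 1L)
      stop("inconsistent d_in across matrices: ",
           paste(unique(d_ins), collapse = ", "), call. = FALSE)
    ok <- vapply(embeddings, function(m) is.matrix(m) && all(is.finite(m)), TRUE)
    if (!all(ok)) stop("non-matrix or non-finite embedding for id(s): ",
                       paste(names(embeddings)[!ok], collapse = ", "), call. = FALSE)
  }
  stored <- lapply(embeddings, t)  # stored orientation: L x d_in
  if (append && file.exists(path)) {
    old <- readRDS(path)
    clash <- intersect(names(old), names(stored))
    if (length(clash) > 0L)
      stop("id(s) already present in container: ",
           paste(clash, collapse = ", "), call. = FALSE)
    stored <- c(old, stored)
  }
  attr(stored, "container") <- "lightattn-embeddings-v1"
  saveRDS(stored, path)
  invisible(path)
}

#' Read an embedding container
#'
#' @param path container file written by [write_embeddings()] (or any RDS of a
#'   named list of 2D matrices).
#' @param ids accessions to load; `NULL` loads everything.
#' @param orientation orientation of the *stored* arrays: `"L_by_d"` (default
#'   container convention) or `"d_by_L"`.
#' @return named list of `d_in x L` matrices (model orientation).
#' @export
read_embeddings <- function(path, ids = NULL, orientation = c("L_by_d", "d_by_L")) {
  orientation <- match.arg(orientation)
  stored <- readRDS(path)
  if (!is.list(stored)) stop("not an embedding container: ", path, call. = FALSE)
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, names(stored))
    if (length(missing_ids) > 0L)
      stop("id(s) absent from container: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    stored <- stored[ids]
  }
  out <- lapply(names(stored), function(id) {
    m <- stored[[id]]
    if (!is.matrix(m) || length(dim(m)) != 2L)
      stop("non-2D array for id ", id, call. = FALSE)
    if (orientation == "L_by_d") t(m) else m
  })
  names(out) <- names(stored)
  if (length(out) > 1L) {
    d_ins <- vapply(out, nrow, 0L)
    if (length(unique(d_ins)) > 1L)
      stop("inconsistent d_in across ids: ",
           paste(unique(d_ins), collapse = ", "), call. = FALSE)
  }
  out
}

#' Drop proteins longer than a maximum length
#'
#' Optional filter for embedders with a hard residue limit. Not applied by any
#' reader automatically; the number of exclusions is reported via `message()`.
#'
#' @param embeddings named list of `d_in x L` matrices.
#' @param max_length maximum residue count to keep.
#' @return filtered list.
#' @export
filter_max_length <- function(embeddings, max_length) {
  keep <- vapply(embeddings, ncol, 0L) <= max_length
  if (any(!keep))
    message(sum(!keep), " protein(s) longer than ", max_length, " residues excluded")
  embeddings[keep]
}

#' Stratified train/validation split
#'
#' Partitions training records into training-only and validation sets,
#' stratified by location class: each class contributes ~`fraction` of its
#' members to validation (rounded; at least one stays in train). Classes with
#' fewer than 2 members stay in train with a warning. Deterministic per seed.
#'
#' @param records data.frame with `id` and `location`; all rows must currently
#'   be `split = "train"` if a `split` column is present.
#' @param fraction validation share, in (0, 1).
#' @param seed integer RNG seed.
#' @return a manifest data.frame with columns `id`, `location`, `split`
#'   (values `train`/`validation`), plus a `class_counts` attribute (table of
#'   class x split).
#' @export
split_train_validation <- function(records, fraction, seed) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            fraction > 0, fraction < 1)
  if ("split" %in% names(records) && !all(records$split == "train"))
    stop("records must all be split='train' before validation splitting",
         call. = FALSE)
  if (anyDuplicated(records$id)) stop("duplicate ids in records", call. = FALSE)
  split <- rep("train", nrow(records))
  set.seed(seed)
  for (cls in sort(unique(records$location))) {
    idx <- which(records$location == cls)
    if (length(idx) < 2L) {
      warning("class '", cls, "' has fewer than 2 members; all kept in train",
              call. = FALSE)
      next
    }
    n_val <- min(round(fraction * length(idx)), length(idx) - 1L)
    if (n_val >= 1L)
      split[sample(idx, n_val)] <- "validation"
  }
  out <- data.frame(id = records$id, location = records$location,
                    split = split, stringsAsFactors = FALSE)
  attr(out, "class_counts") <- table(out$location, out$split)
  out
}

#' Write a split manifest as TSV (`id <TAB> split`)
#' @param manifest data.frame with `id` and `split`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("id", "split")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
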