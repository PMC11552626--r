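# File formats: FASTA (optionally with inline "@"/"&" tokens), site TSV,
# split manifests, prediction CSV.

#' Read FASTA, extracting inline mod tokens into a label channel
#'
#' Sequences may contain `"@"`/`"&"` at known modified positions (the web
#' input convention). Tokens are recorded as 1-based sites of a label channel
#' and replaced internally by their unlabeled residues, so that labeling is
#' controlled uniformly by [apply_labels()] downstream. Plain FASTA yields an
#' empty channel.
#'
#' @param path FASTA file.
#' @param alphabet `mod_alphabet` defining the token semantics; required when
#'   the file contains mod tokens.
#' @param strict Passed to [normalize_sequence()].
#' @return List with `sequences` (named character, unlabeled), `channel`
#'   (a [label_channel()], possibly with no sites; `NULL` when no alphabet
#'   with mod tokens was supplied), and `headers`.
#' @export
read_fasta_tokens <- function(path, alphabet = NULL, strict = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- as.character(ss)
  names(seqs) <- ids

  tok_pool <- if (is.null(alphabet)) MOD_TOKEN_POOL else mod_tokens(alphabet)
  sites <- list()
  out <- character(length(seqs))
  names(out) <- ids
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    hit <- chars %in% MOD_TOKEN_POOL
    if (any(hit)) {
      if (is.null(alphabet) || nrow(alphabet$mod_map) == 0L) {
        stop("sequence '", ids[i], "' contains mod token '",
             chars[hit][1L], "' but the model alphabet defines no mod tokens")
      }
      bad <- chars[hit][!(chars[hit] %in% tok_pool)]
      if (length(bad)) {
        stop("sequence '", ids[i], "': token '", bad[1L],
             "' is not defined by the model alphabet")
      }
      pos <- which(hit)
      res <- vapply(chars[pos], function(tk) {
        r <- mod_token_residue(alphabet, tk)
        if (is.na(r)) {
          stop("sequence '", ids[i], "': token '", tk, "' at position ",
               which(chars == tk)[1L], " maps to more than one residue; ",
               "inline-token input requires per-residue tokens")
        }
        r
      }, "")
      chars[pos] <- res
      sites[[ids[i]]] <- pos
    }
    out[[i]] <- normalize_sequence(paste0(chars, collapse = ""),
                                   strict = strict, warn = FALSE)
  }
  channel <- NULL
  if (!is.null(alphabet) && nrow(alphabet$mod_map)) {
    channel <- label_channel(name = alphabet$mod_map$channel[1L],
                             targets = unique(alphabet$mod_map$residue),
                             sites = sites)
  }
  list(sequences = out, channel = channel, headers = headers)
}

#' Write sequences (possibly containing mod tokens) as FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a site-annotation TSV (protein_id, position, mod_type)
#' @param path TSV file with header.
#' @return data.frame with columns protein_id, position (integer, 1-based),
#'   mod_type.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "mod_type")
  if (!all(need %in% names(df))) {
    stop("site TSV must have columns ", paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$protein_id <- as.character(df$protein_id)
  df[need]
}

#' Write a site-annotation TSV
#' @param sites data.frame with protein_id, position, mod_type.
#' @param path Output file.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Turn a site data.frame into a label channel
#' @param sites data.frame (protein_id, position, mod_type) or path to TSV.
#' @param name Channel name; defaults to the (single) mod_type present.
#' @param targets Residues eligible for the modification.
#' @export
sites_as_channel <- function(sites, targets, name = NULL) {
  if (is.character(sites) && length(sites) == 1L) sites <- read_sites(sites)
  if (is.null(name)) {
    mt <- unique(sites$mod_type)
    if (length(mt) != 1L) {
      stop("sites carry ", length(mt), " mod types; supply `name` and filter")
    }
    name <- mt
  } else if ("mod_type" %in% names(sites)) {
    sites <- sites[sites$mod_type == name, , drop = FALSE]
  }
  label_channel(name = name, targets = targets, sites = sites)
}

#' Write a split manifest (fold, partition, protein_id, position, label)
#'
#' The manifest pins the exact membership of every partition of every fold so
#' a run can be reproduced record-for-record.
#'
#' @param splits A `dataset_split` or list of them (one per fold).
#' @param path Output TSV.
#' @export
write_split_manifest <- function(splits, path) {
  if (inherits(splits, "dataset_split")) splits <- list(splits)
  rows <- lapply(seq_along(splits), function(f) {
    sp <- splits[[f]]
    do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
      info <- sp[[p]]$info
      if (nrow(info) == 0L) return(NULL)
      data.frame(fold = f, partition = p, protein_id = info$protein_id,
                 position = info$position, label = info$label,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a split manifest written by [write_split_manifest()]
#' @param path Manifest TSV.
#' @return data.frame(fold, partition, protein_id, position, label).
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df
}

#' Write prediction rows as CSV
#' @param rows data.frame with protein_id, position, residue, probability,
#'   model_id, call.
#' @param path Output CSV.
#' @export
write_predictions <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
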