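# Token alphabet with modified-residue symbols, window extraction, and
# integer (de)vectorization.

#' Canonical amino-acid symbols, alphabetically ordered
#' @keywords internal
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_TOKEN <- "-"
SEC_TOKEN <- "U"
MOD_TOKEN_POOL <- c("@", "&")

# residues without a dedicated code; mapped to the padding token on input
NONSTANDARD_RESIDUES <- c("X", "B", "Z", "J", "O", "*", ".")

#' Define a label channel for one modification type
#'
#' A label channel names a modification (e.g. `"phospho-ST"`), the residues
#' that can carry it, and the known modified positions per protein. Channels
#' drive both the construction of the token alphabet and the substitution of
#' known sites by mod tokens before window extraction.
#'
#' @param name Modification-type name.
#' @param targets Character vector of single-letter residues eligible for the
#'   modification (e.g. `c("S", "T")`).
#' @param sites Known modified positions: either a named list of 1-based
#'   integer vectors keyed by protein id, a data.frame with columns
#'   `protein_id` and `position`, or a bare integer vector (single unnamed
#'   sequence).
#' @return An object of class `label_channel`.
#' @export
label_channel <- function(name, targets, sites = list()) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  targets <- toupper(as.character(targets))
  if (!all(targets %in% AA_CANONICAL)) {
    stop("label_channel targets must be canonical amino acids, got: ",
         paste(setdiff(targets, AA_CANONICAL), collapse = ", "))
  }
  if (is.data.frame(sites)) {
    sites <- split(as.integer(sites$position), as.character(sites$protein_id))
  } else if (is.numeric(sites)) {
    sites <- list(. = as.integer(sites))
  }
  sites <- lapply(sites, function(p) sort(unique(as.integer(p))))
  structure(list(name = name, targets = targets, sites = sites),
            class = "label_channel")
}

#' @export
print.label_channel <- function(x, ...) {
  cat(sprintf("label channel '%s' on {%s}: %d sites in %d proteins\n",
              x$name, paste(x$targets, collapse = ","),
              sum(lengths(x$sites)), length(x$sites)))
  invisible(x)
}

channel_sites_for <- function(channel, protein_id) {
  if (is.null(protein_id)) {
    if (length(channel$sites) == 0L) return(integer(0))
    if (length(channel$sites) == 1L) return(channel$sites[[1L]])
    stop("protein_id required: channel '", channel$name,
         "' carries sites for multiple proteins")
  }
  channel$sites[[protein_id]] %||% integer(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the token alphabet, assigning mod tokens to label channels
#'
#' The base vocabulary is `"-"` (no amino acid, code 0), the 20 canonical
#' amino acids alphabetically (codes 1..20, so A->1, C->2, D->3) and `"U"`
#' for selenocysteine (code 21). Each (channel, residue-class) needing a
#' token consumes `"@"` first, then `"&"`; at most two mod tokens exist.
#' With `per_residue_tokens = TRUE` (default) a two-residue channel such as
#' phospho-S/T uses `"@"` for the first residue and `"&"` for the second;
#' otherwise one token covers the whole channel.
#'
#' @param channels List of [label_channel()] objects to be encoded.
#' @param per_residue_tokens Give each residue type of a channel its own
#'   token (default) rather than one token per channel.
#' @param embedding_dim Length of the learned embedding vectors (default 21).
#' @return An object of class `mod_alphabet` with fields `tokens`, `index`
#'   (token -> 0-based integer code), `mod_map` (data.frame channel/residue/
#'   token), `vocab_size`, `embedding_dim`.
#' @examples
#' ab <- build_alphabet()
#' vectorize("ACD", ab)  # 1 2 3
#' @export
build_alphabet <- function(channels = list(), per_residue_tokens = TRUE,
                           embedding_dim = 21L) {
  if (inherits(channels, "label_channel")) channels <- list(channels)
  stopifnot(all(vapply(channels, inherits, TRUE, "label_channel")))
  map <- list()
  for (ch in channels) {
    if (per_residue_tokens && length(ch$targets) > 1L) {
      for (r in ch$targets) {
        map[[length(map) + 1L]] <- data.frame(channel = ch$name, residue = r,
                                              stringsAsFactors = FALSE)
      }
    } else {
      map[[length(map) + 1L]] <- data.frame(channel = ch$name,
                                            residue = ch$targets,
                                            stringsAsFactors = FALSE)
    }
  }
  n_tokens_needed <- length(map)
  if (n_tokens_needed > length(MOD_TOKEN_POOL)) {
    offending <- unique(vapply(map, function(m) m$channel[1L], ""))
    stop("label channels require ", n_tokens_needed, " mod tokens but only ",
         length(MOD_TOKEN_POOL), " (", paste(MOD_TOKEN_POOL, collapse = ", "),
         ") are defined; offending channels: ",
         paste(offending, collapse = ", "))
  }
  mod_map <- if (n_tokens_needed) {
    do.call(rbind, lapply(seq_along(map), function(i) {
      cbind(map[[i]], token = MOD_TOKEN_POOL[i], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(channel = character(0), residue = character(0),
               token = character(0), stringsAsFactors = FALSE)
  }
  tokens <- c(PAD_TOKEN, AA_CANONICAL, SEC_TOKEN, unique(mod_map$token))
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index = index, mod_map = mod_map,
                 vocab_size = length(tokens),
                 embedding_dim = as.integer(embedding_dim),
                 per_residue_tokens = per_residue_tokens),
            class = "mod_alphabet")
}

#' @export
print.mod_alphabet <- function(x, ...) {
  cat(sprintf("mod_alphabet: %d tokens, embedding dim %d\n",
              x$vocab_size, x$embedding_dim))
  if (nrow(x$mod_map)) {
    for (i in seq_len(nrow(x$mod_map))) {
      cat(sprintf("  '%s' = %s on %s\n", x$mod_map$token[i],
                  x$mod_map$channel[i], x$mod_map$residue[i]))
    }
  }
  invisible(x)
}

mod_tokens <- function(alphabet) unique(alphabet$mod_map$token)

mod_token_for <- function(alphabet, channel_name, residue) {
  m <- alphabet$mod_map
  hit <- m$channel == channel_name & m$residue == residue
  if (!any(hit)) return(NA_character_)
  m$token[which(hit)[1L]]
}

# token -> residue; NA when the token is ambiguous (single-token channel
# over several residues)
mod_token_residue <- function(alphabet, token) {
  r <- unique(alphabet$mod_map$residue[alphabet$mod_map$token == token])
  if (length(r) == 1L) r else NA_character_
}

#' Normalize a raw protein sequence
#'
#' Uppercases and maps non-standard residue codes (X, B, Z, J, O, '*', '.')
#' to the no-amino-acid token `"-"`. In strict mode such residues are an
#' error instead.
#'
#' @param sequence Residue string.
#' @param strict Error on non-standard residues instead of masking them.
#' @param warn Emit a warning when residues are masked.
#' @return Normalized residue string.
#' @export
normalize_sequence <- function(sequence, strict = FALSE, warn = TRUE) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- chars %in% NONSTANDARD_RESIDUES
  if (any(bad)) {
    if (strict) {
      stop("non-standard residues at positions ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " (", paste(unique(chars[bad]), collapse = ","), ")")
    }
    if (warn) {
      warning(sum(bad), " non-standard residue(s) (",
              paste(unique(chars[bad]), collapse = ","),
              ") normalized to '-'")
    }
    chars[bad] <- PAD_TOKEN
  }
  paste0(chars, collapse = "")
}

#' Substitute known modified residues by their mod tokens
#'
#' Each site position listed in a channel has its residue replaced by the
#' channel's mod token; all other positions are untouched and length is
#' preserved.
#'
#' @param sequence Unlabeled residue string.
#' @param channels List of [label_channel()]s (or a single channel).
#' @param alphabet A [build_alphabet()] result that encodes the channels.
#' @param protein_id Protein id used to look up sites in the channels; may be
#'   `NULL` when channels carry a bare site vector.
#' @return Labeled residue string.
#' @export
apply_labels <- function(sequence, channels, alphabet, protein_id = NULL) {
  if (inherits(channels, "label_channel")) channels <- list(channels)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  for (ch in channels) {
    pos <- channel_sites_for(ch, protein_id)
    if (length(pos) == 0L) next
    if (any(pos < 1L | pos > n)) {
      stop("site position out of range for protein '",
           protein_id %||% "?", "': ",
           paste(pos[pos < 1L | pos > n], collapse = ", "))
    }
    res <- chars[pos]
    bad <- !(res %in% ch$targets)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("channel '", ch$name, "' site at protein '",
           protein_id %||% "?", "' position ", pos[i], " is residue '",
           res[i], "', not one of {", paste(ch$targets, collapse = ","), "}")
    }
    tok <- vapply(res, function(r) mod_token_for(alphabet, ch$name, r), "")
    if (anyNA(tok)) {
      stop("channel '", ch$name, "' has no mod token in the alphabet")
    }
    chars[pos] <- tok
  }
  paste0(chars, collapse = "")
}

#' Extract a fixed-length window centered on a candidate site
#'
#' Returns the k-mer centered at `center`, padding out-of-sequence positions
#' with `"-"`. The center position is always emitted as the *unlabeled*
#' target residue, even if that site appears in a label channel: the center's
#' own modification status is the prediction target, not an input.
#'
#' @param labeled_sequence Residue string, possibly containing mod tokens.
#' @param center 1-based center position.
#' @param k Odd window length (default 53).
#' @param alphabet A `mod_alphabet`.
#' @param center_residue Unlabeled residue at the center; required only when
#'   the center carries an ambiguous mod token.
#' @param protein_id,position Optional origin metadata stored on the window.
#' @return An object of class `encoded_window` with fields `tokens` (string
#'   of length k), `codes` (integer vector), `center_index`, `origin`.
#' @export
extract_window <- function(labeled_sequence, center, k = 53L, alphabet,
                           center_residue = NULL, protein_id = NULL,
                           position = NULL) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("window length k must be odd, got ", k)
  chars <- strsplit(labeled_sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (center < 1L || center > n) {
    stop("center ", center, " out of range 1..", n)
  }
  w <- (k - 1L) %/% 2L
  padded <- c(rep(PAD_TOKEN, w), chars, rep(PAD_TOKEN, w))
  win <- padded[center:(center + 2L * w)]
  ci <- w + 1L
  if (win[ci] %in% mod_tokens(alphabet)) {
    if (is.null(center_residue)) {
      center_residue <- mod_token_residue(alphabet, win[ci])
      if (is.na(center_residue)) {
        stop("center carries ambiguous mod token '", win[ci],
             "'; supply center_residue")
      }
    }
    win[ci] <- center_residue
  }
  tokens <- paste0(win, collapse = "")
  structure(list(tokens = tokens,
                 codes = vectorize(tokens, alphabet),
                 center_index = ci,
                 origin = list(protein_id = protein_id,
                               position = position %||% center)),
            class = "encoded_window")
}

#' Convert a token string to integer codes
#'
#' Uses the alphabet's fixed code assignment: `"-"` -> 0, A -> 1, C -> 2,
#' D -> 3, ..., Y -> 20, `"U"` -> 21, then mod tokens.
#'
#' @param tokens Token string over the alphabet.
#' @param alphabet A `mod_alphabet`.
#' @return Integer vector, one code per token.
#' @export
vectorize <- function(tokens, alphabet) {
  chars <- strsplit(tokens, "", fixed = TRUE)[[1L]]
  codes <- unname(alphabet$index[chars])
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop("unknown token '", chars[i], "' at position ", i)
  }
  codes
}

#' Convert integer codes back to a token string
#' @param codes Integer vector of codes in `0..vocab_size-1`.
#' @param alphabet A `mod_alphabet`.
#' @return Token string.
#' @export
devectorize <- function(codes, alphabet) {
  if (any(codes < 0L | codes >= alphabet$vocab_size)) {
    stop("code out of range 0..", alphabet$vocab_size - 1L)
  }
  paste0(alphabet$tokens[codes + 1L], collapse = "")
}
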