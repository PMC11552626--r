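# Synthetic proteome generator with planted sequence motifs and PTM
# crosstalk, so every pipeline stage is testable offline.
#
# Generative model (documented in the methods vignette):
#   1. Sequences are i.i.d. draws from the background residue distribution.
#   2. Each target-residue occurrence is a candidate; the total number of
#      positives is Binomial(n_targets, base_rate).
#   3. A fraction `ptm_dependence` of positives come in nearby *pairs*: one
#      anchor placed uniformly, one partner placed at a signed offset drawn
#      with probability proportional to 1/|offset| from `dependence_offsets`
#      (the decaying proximity pattern). The remaining positives are
#      isolated. In "cross" channel mode the partner belongs to a second
#      modification type instead of the positive class.
#   4. A sequence motif is written around every *anchor* positive: each
#      motif position is set to its consensus residue independently with
#      probability `match_prob` (never overwriting another planted site).
#      Partner sites carry no motif of their own: they are modified because
#      of crosstalk with the anchor, not because of their sequence context,
#      so their positive status is only discoverable through the label
#      channel (or the anchor's nearby context).
#   5. The known-site label channel is the positive list (or the cross-site
#      list) with each site dropped independently with probability
#      `label_noise`, emulating database incompleteness.

# UniProt-like background residue frequencies (percent), AA_CANONICAL order
BG_UNIPROT <- c(8.25, 1.37, 5.45, 6.75, 3.86, 7.07, 2.27, 5.96, 5.84, 9.66,
                2.42, 4.06, 4.70, 3.93, 5.53, 6.56, 5.34, 6.87, 1.08, 2.92)

#' Specify a synthetic proteome
#'
#' Defaults state the desk-scale world used throughout the test suite:
#' 300 proteins of length 200-400, uniform residue background, phospho-like
#' S/T target class at a 5% positive base rate, a moderately informative
#' 4-position consensus motif, 70% of positives paired with a nearby known
#' site (offsets up to +/-5, nearer offsets more likely), and 20% of known
#' sites missing from the label channel.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (min must be >= k in use).
#' @param background `"uniform"` over the 20 canonical residues, or
#'   `"uniprot"` for natural-abundance-like frequencies.
#' @param residue_targets Residues carrying the modification.
#' @param mod_name Modification-type name for outputs.
#' @param motif List with `offsets`, `residues`, `match_prob`: consensus
#'   written around each positive, per-position Bernoulli(match_prob).
#' @param ptm_dependence Fraction of positives that have a known PTM planted
#'   at a nearby offset.
#' @param dependence_offsets Signed offsets eligible for the planted partner.
#' @param label_noise Probability that a known site is absent from the label
#'   channel.
#' @param base_rate Fraction of target residues that are positive.
#' @param channel_mode `"same"` (partners are positives of the same type;
#'   the channel is the positive list) or `"cross"` (partners form a second,
#'   independent modification channel).
#' @param seed Integer seed; output is a pure function of the spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_proteins = 300L, length_range = c(200L, 400L),
                            background = c("uniform", "uniprot"),
                            residue_targets = c("S", "T"),
                            mod_name = "phospho-ST",
                            motif = list(offsets = c(-3L, -2L, 1L, 2L),
                                         residues = c("R", "R", "P", "L"),
                                         match_prob = 0.4),
                            ptm_dependence = 0.7,
                            dependence_offsets = c(-5:-1, 1:5),
                            label_noise = 0.2, base_rate = 0.05,
                            channel_mode = c("same", "cross"), seed = 1L) {
  background <- match.arg(background)
  channel_mode <- match.arg(channel_mode)
  probs <- c(ptm_dependence = ptm_dependence, label_noise = label_noise,
             base_rate = base_rate, match_prob = motif$match_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  stopifnot(length(motif$offsets) == length(motif$residues),
            all(motif$offsets != 0L),
            all(dependence_offsets != 0L),
            length(length_range) == 2L, length_range[1L] <= length_range[2L])
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background = background,
                 residue_targets = toupper(residue_targets),
                 mod_name = mod_name, motif = motif,
                 ptm_dependence = ptm_dependence,
                 dependence_offsets = as.integer(dependence_offsets),
                 label_noise = label_noise, base_rate = base_rate,
                 channel_mode = channel_mode, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic proteome with planted PTM signal
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional directory; when given, writes `proteome.fasta`,
#'   `positives.tsv`, `known_sites.tsv` and `manifest.json` (byte-identical
#'   across runs with the same spec).
#' @return List with `sequences` (named character), `positives`
#'   (data.frame protein_id/position/mod_type), `channel` (the noisy
#'   known-site [label_channel()]), `cross_channel` (in `"cross"` mode),
#'   and `manifest` (every planted signal: pairs, dropped labels, counts).
#' @export
simulate_proteome <- function(spec = simulation_spec(), dir = NULL) {
  bg <- if (spec$background == "uniform") rep(1 / 20, 20) else
    BG_UNIPROT / sum(BG_UNIPROT)
  res <- withr::with_seed(spec$seed, simulate_impl(spec, bg))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(res$sequences, file.path(dir, "proteome.fasta"))
    write_sites(res$positives, file.path(dir, "positives.tsv"))
    write_sites(res$known_sites, file.path(dir, "known_sites.tsv"))
    jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

simulate_impl <- function(spec, bg) {
  n <- spec$n_proteins
  lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]), n,
                 replace = TRUE)
  ids <- sprintf("sim%04d", seq_len(n))
  chars <- lapply(lens, function(L) sample(AA_CANONICAL, L, replace = TRUE,
                                           prob = bg))
  names(chars) <- ids

  targets <- do.call(rbind, lapply(ids, function(pid) {
    pos <- which(chars[[pid]] %in% spec$residue_targets)
    if (length(pos) == 0L) return(NULL)
    data.frame(protein_id = pid, position = pos, stringsAsFactors = FALSE)
  }))
  n_targets <- nrow(targets)
  if (is.null(n_targets) || n_targets == 0L) stop("no target residues generated")

  n_pos <- stats::rbinom(1L, n_targets, spec$base_rate)
  if (n_pos == 0L) stop("base_rate ", spec$base_rate, " produced no positives")
  # at full dependence every positive must belong to a pair: force evenness
  if (spec$ptm_dependence == 1 && n_pos %% 2L == 1L && n_pos > 1L) {
    n_pos <- n_pos - 1L
  }
  n_pairs <- round(spec$ptm_dependence * n_pos / 2)
  n_anchor <- n_pos - n_pairs
  anchor_idx <- sample.int(n_targets, n_anchor)
  pair_anchors <- anchor_idx[sample.int(n_anchor, n_pairs)]

  pos_set <- new.env(parent = emptyenv())   # "pid:pos" -> TRUE
  key <- function(pid, p) paste0(pid, ":", p)
  for (i in anchor_idx) {
    assign(key(targets$protein_id[i], targets$position[i]), TRUE, pos_set)
  }

  off_prob <- (1 / abs(spec$dependence_offsets))
  pairs <- list()
  partners <- list()
  failed_anchors <- integer(0)
  for (i in pair_anchors) {
    pid <- targets$protein_id[i]
    p <- targets$position[i]
    L <- length(chars[[pid]])
    cand <- sample(spec$dependence_offsets, length(spec$dependence_offsets),
                   prob = off_prob)
    placed <- FALSE
    for (d in cand) {
      q <- p + d
      if (q < 1L || q > L) next
      if (exists(key(pid, q), pos_set)) next
      if (!(chars[[pid]][q] %in% spec$residue_targets)) {
        chars[[pid]][q] <- sample(spec$residue_targets, 1L)
      }
      partners[[length(partners) + 1L]] <-
        data.frame(protein_id = pid, position = q, stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <-
        data.frame(protein_id = pid, anchor = p, partner = q, offset = d,
                   stringsAsFactors = FALSE)
      if (spec$channel_mode == "same") assign(key(pid, q), TRUE, pos_set)
      placed <- TRUE
      break
    }
    if (!placed) {
      # no room for a partner: the anchor does not become a positive, so
      # the pairing invariant stays exact
      failed_anchors <- c(failed_anchors, i)
      rm(list = key(pid, p), envir = pos_set)
    }
  }
  if (length(failed_anchors)) {
    anchor_idx <- setdiff(anchor_idx, failed_anchors)
  }
  partners <- if (length(partners)) do.call(rbind, partners) else
    data.frame(protein_id = character(0), position = integer(0))
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(protein_id = character(0), anchor = integer(0),
               partner = integer(0), offset = integer(0))

  anchors <- targets[anchor_idx, , drop = FALSE]
  positives <- if (spec$channel_mode == "same") {
    rbind(anchors, partners)
  } else {
    anchors
  }
  positives <- positives[order(positives$protein_id, positives$position), ,
                         drop = FALSE]
  rownames(positives) <- NULL

  # motif planting around anchors only, guarded so a planted site residue
  # is never overwritten
  is_protected <- function(pid, p) {
    exists(key(pid, p), pos_set) ||
      any(partners$protein_id == pid & partners$position == p)
  }
  motif_sites <- anchors
  for (r in seq_len(nrow(motif_sites))) {
    pid <- motif_sites$protein_id[r]
    p <- motif_sites$position[r]
    L <- length(chars[[pid]])
    for (mi in seq_along(spec$motif$offsets)) {
      q <- p + spec$motif$offsets[mi]
      if (q < 1L || q > L || is_protected(pid, q)) next
      if (stats::runif(1L) < spec$motif$match_prob) {
        chars[[pid]][q] <- spec$motif$residues[mi]
      }
    }
  }

  sequences <- vapply(chars, paste0, "", collapse = "")

  known_source <- if (spec$channel_mode == "same") positives else partners
  kept <- stats::runif(nrow(known_source)) >= spec$label_noise
  known <- known_source[kept, , drop = FALSE]
  channel_name <- if (spec$channel_mode == "same") spec$mod_name else
    paste0(spec$mod_name, "-cross")
  channel <- label_channel(channel_name, spec$residue_targets, known)

  positives$mod_type <- spec$mod_name
  known$mod_type <- channel_name

  manifest <- list(
    spec = unclass(spec), n_targets = n_targets, n_positives = nrow(positives),
    n_pairs = nrow(pairs), n_known = nrow(known),
    n_dropped_labels = nrow(known_source) - nrow(known),
    pairs = pairs, generated = "synthetic proteome (no real organism)")

  list(sequences = sequences, positives = positives,
       known_sites = known, channel = channel,
       cross_channel = if (spec$channel_mode == "cross") channel else NULL,
       manifest = manifest)
}
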