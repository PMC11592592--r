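# Synthetic hairpin generator. Emulates the construction of a balanced
# pre-miRNA benchmark: positives are single stem-loop molecules with a
# high Watson-Crick pair fraction, a terminal loop and occasional bulges;
# negatives are dinucleotide-shuffled positives refolded with a simple
# dynamic-programming fallback, hairpins with a forced low pair fraction,
# or truncated short hairpins. All structural parameters realized during
# generation are planted in the record id for exact-recovery tests.

#' Configuration for the synthetic hairpin generator
#'
#' Defaults describe a plausible pre-miRNA-like regime: stems of 18-45
#' paired columns, terminal loops of 3-15 nt, mostly Watson-Crick stems
#' and sparse small bulges, in a class-balanced dataset.
#'
#' @param n_samples number of records to generate
#' @param stem_length_range integer range of paired stem columns
#' @param loop_length_range integer range of terminal loop lengths (nt)
#' @param pair_fraction_range range in \[0,1\] for the fraction of stem
#'   pairs that are Watson-Crick (strong); the rest are G-U wobbles
#' @param bulge_rate per-junction probability of an unpaired bulge
#' @param max_bulge_size largest bulge run (nt)
#' @param class_balance fraction of positive (pre-miRNA) records
#' @param seed RNG seed; identical seed and config give identical output
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 200L,
                             stem_length_range = c(18L, 45L),
                             loop_length_range = c(3L, 15L),
                             pair_fraction_range = c(0.75, 1.0),
                             bulge_rate = 0.1,
                             max_bulge_size = 4L,
                             class_balance = 0.5,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              stem_length_range = as.integer(stem_length_range),
              loop_length_range = as.integer(loop_length_range),
              pair_fraction_range = as.numeric(pair_fraction_range),
              bulge_rate = bulge_rate, max_bulge_size = as.integer(max_bulge_size),
              class_balance = class_balance, seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 0,
            length(cfg$stem_length_range) == 2L,
            cfg$stem_length_range[1] <= cfg$stem_length_range[2],
            cfg$stem_length_range[1] >= 1L,
            length(cfg$loop_length_range) == 2L,
            cfg$loop_length_range[1] <= cfg$loop_length_range[2],
            cfg$loop_length_range[1] >= 3L,
            length(cfg$pair_fraction_range) == 2L,
            cfg$pair_fraction_range[1] <= cfg$pair_fraction_range[2],
            cfg$pair_fraction_range[1] >= 0, cfg$pair_fraction_range[2] <= 1,
            cfg$bulge_rate >= 0, cfg$bulge_rate <= 1,
            cfg$max_bulge_size >= 1L,
            cfg$class_balance >= 0, cfg$class_balance <= 1)
  if (cfg$stem_length_range[1] + ceiling(cfg$loop_length_range[1] / 2) > 100L) {
    stop("range conflict: smallest stem + loop already exceeds the ",
         "100-column image budget")
  }
  class(cfg) <- "generator_config"
  cfg
}

STRONG_PAIRS <- rbind(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
WOBBLE_PAIRS <- rbind(c("G", "U"), c("U", "G"))

# assemble sequence + dot-bracket from stem description
build_hairpin <- function(top, bottom, structure_top, structure_bottom, loop_nts) {
  seq <- paste0(paste(top, collapse = ""), paste(loop_nts, collapse = ""),
                paste(rev(bottom), collapse = ""))
  db <- paste0(paste(structure_top, collapse = ""),
               strrep(".", length(loop_nts)),
               paste(rev(structure_bottom), collapse = ""))
  list(sequence = seq, structure = db)
}

#' Generate one positive stem-loop record
#'
#' Draws stem length, loop length, Watson-Crick pair fraction and bulges
#' from `config` and assembles a single stem-loop whose realized values
#' are recorded in the id (see [planted_meta()]). Uses the current RNG
#' state; seed the stream with `set.seed()` or use [generate_dataset()].
#'
#' @param config a [generator_config()]
#' @param id record identifier stem
#' @return A positive `structured_rna`.
#' @export
generate_hairpin <- function(config, id = "pos") {
  for (attempt in 1:100) {
    S <- sample_range(config$stem_length_range)
    L <- sample_range(config$loop_length_range)
    pf <- stats::runif(1, config$pair_fraction_range[1], config$pair_fraction_range[2])
    n_strong <- round(pf * S)
    # bulge events at junctions between consecutive stem pairs
    r5 <- integer(max(S - 1L, 0L)); r3 <- integer(max(S - 1L, 0L))
    if (S > 1L && config$bulge_rate > 0) {
      hit <- stats::runif(S - 1L) < config$bulge_rate
      for (j in which(hit)) {
        if (stats::runif(1) < 0.3) {  # two-sided internal loop
          r5[j] <- sample.int(config$max_bulge_size, 1L)
          r3[j] <- sample.int(config$max_bulge_size, 1L)
        } else if (stats::runif(1) < 0.5) {
          r5[j] <- sample.int(config$max_bulge_size, 1L)
        } else {
          r3[j] <- sample.int(config$max_bulge_size, 1L)
        }
      }
    }
    n_cols <- S + sum(r5) + sum(r3) + ceiling(L / 2)
    if (n_cols <= 100L) break
    if (attempt == 100L) {
      stop("range conflict: stem + loop + bulges cannot fit in 100 ",
           "encoded columns under this configuration")
    }
  }
  strong_at <- rep(FALSE, S)
  strong_at[sample.int(S, n_strong)] <- TRUE
  top <- character(0); bottom <- character(0)
  st <- character(0); sb <- character(0)
  for (j in seq_len(S)) {
    pair <- if (strong_at[j]) {
      STRONG_PAIRS[sample.int(4L, 1L), ]
    } else {
      WOBBLE_PAIRS[sample.int(2L, 1L), ]
    }
    top <- c(top, pair[1]); bottom <- c(bottom, pair[2])
    st <- c(st, "("); sb <- c(sb, ")")
    if (j < S && (r5[j] > 0 || r3[j] > 0)) {
      if (r5[j] > 0) {
        top <- c(top, random_nts(r5[j])); st <- c(st, rep(".", r5[j]))
      }
      if (r3[j] > 0) {
        bottom <- c(bottom, random_nts(r3[j])); sb <- c(sb, rep(".", r3[j]))
      }
    }
  }
  hp <- build_hairpin(top, bottom, st, sb, random_nts(L))
  runs <- c(r5, r3); runs <- runs[runs > 0]
  asym <- abs(r5 - r3)
  meta <- sprintf("%s|mech=hairpin|stem=%d|loop=%d|pf=%.12f|nb=%d|mb=%d|asym=%d",
                  id, S, L, n_strong / S, length(runs),
                  if (length(runs)) max(runs) else 0L,
                  if (length(asym)) max(asym) else 0L)
  structured_rna(meta, hp$sequence, hp$structure, label = 1L)
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)

random_nts <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence uniformly among those
#' with identical dinucleotide (doublet) composition, the standard way to
#' build RNA decoys that preserve stacking statistics.
#'
#' @param sequence character string
#' @return Shuffled string with the same first and last letter and the
#'   same dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n <= 3L) return(sequence)
  verts <- unique(s)
  edges <- lapply(verts, function(v) s[which(s[-n] == v) + 1L])
  names(edges) <- verts
  last <- s[n]
  # pick a random last exit edge per vertex; accept when they form a tree into `last`
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- v; cur <- v
      repeat {
        cur <- last_edge[[cur]]
        if (is.na(cur) || cur == last) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  # order each vertex's edge multiset randomly, forcing the chosen edge last
  pool <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      e <- e[-match(last_edge[[v]], e)]
      c(sample(e), last_edge[[v]])
    } else sample(e)
  })
  names(pool) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  for (i in 2:n) {
    v <- out[i - 1L]
    used[[v]] <- used[[v]] + 1L
    out[i] <- pool[[v]][used[[v]]]
  }
  paste(out, collapse = "")
}

#' Fold a sequence into its best single stem-loop (DP fallback)
#'
#' A lightweight replacement for thermodynamic folding: the 5' half is
#' aligned against the reversed 3' half by Needleman-Wunsch with pair
#' scores (Watson-Crick +3, G-U wobble +1, other juxtapositions -1,
#' gap -1), reserving a minimal 3-nt terminal loop at the midpoint. The
#' result is always a valid nested single stem-loop; it deliberately
#' ignores thermodynamics, which is what makes refolded shuffles
#' "suboptimal" decoys.
#'
#' @param sequence RNA string
#' @return Dot-bracket string of the same length.
#' @export
fold_hairpin <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 8L) return(strrep(".", n))
  n5 <- (n - 3L) %/% 2L
  arm5 <- s[1:n5]
  i3 <- (n5 + 4L):n
  arm3 <- rev(s[i3])
  a <- length(arm5); b <- length(arm3)
  pair_score <- function(x, y) {
    if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) 3
    else if ((x == "G" && y == "U") || (x == "U" && y == "G")) 1
    else -1
  }
  gp <- -1
  F <- matrix(0, a + 1L, b + 1L)
  F[, 1] <- gp * (0:a); F[1, ] <- gp * (0:b)
  for (i in 1:a) {
    for (j in 1:b) {
      F[i + 1, j + 1] <- max(F[i, j] + pair_score(arm5[i], arm3[j]),
                             F[i, j + 1] + gp, F[i + 1, j] + gp)
    }
  }
  db <- rep(".", n)
  i <- a; j <- b
  while (i > 0 && j > 0) {
    if (F[i + 1, j + 1] == F[i, j] + pair_score(arm5[i], arm3[j])) {
      if (pair_score(arm5[i], arm3[j]) > 0) {
        db[i] <- "("
        db[i3[b - j + 1L]] <- ")"  # arm3 index j is reversed position
      }
      i <- i - 1L; j <- j - 1L
    } else if (F[i + 1, j + 1] == F[i, j + 1] + gp) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  paste(db, collapse = "")
}

#' Generate one negative (non-pre-miRNA) record
#'
#' One of three mechanisms, chosen uniformly at random and recorded in the
#' id: `shuffle` (dinucleotide shuffle of a freshly drawn positive,
#' refolded with [fold_hairpin()]), `lowpair` (hairpin with pair fraction
#' forced at or below `pf_ceiling`), or `short` (truncated hairpin, stem
#' 3-8 and loop 3-6 nt).
#'
#' @param config a [generator_config()]
#' @param id record identifier stem
#' @param pf_ceiling pair-fraction ceiling for the `lowpair` mechanism
#' @return A negative `structured_rna`.
#' @export
generate_negative <- function(config, id = "neg", pf_ceiling = 0.3) {
  mech <- sample(c("shuffle", "lowpair", "short"), 1L)
  if (mech == "shuffle") {
    pos <- generate_hairpin(config, id = "tmp")
    seqs <- dinucleotide_shuffle(pos$sequence)
    db <- fold_hairpin(seqs)
    rna <- structured_rna(sprintf("%s|mech=shuffle", id), seqs, db, label = 0L)
  } else if (mech == "lowpair") {
    cfg <- config
    cfg$pair_fraction_range <- c(0.05, pf_ceiling)
    # the planted count is rounded, so redraw the rare realization that
    # rounds above the ceiling
    for (i in 1:50) {
      rna <- generate_hairpin(cfg, id = id)
      if (planted_meta(rna)$pf <= pf_ceiling) break
    }
    rna$label <- 0L
    rna$id <- sub("mech=hairpin", "mech=lowpair", rna$id)
  } else {
    cfg <- config
    cfg$stem_length_range <- c(3L, 8L)
    cfg$loop_length_range <- c(3L, 6L)
    cfg$bulge_rate <- 0
    rna <- generate_hairpin(cfg, id = id)
    rna$label <- 0L
    rna$id <- sub("mech=hairpin", "mech=short", rna$id)
  }
  rna
}

#' Generate a labeled synthetic dataset
#'
#' Exactly `round(n_samples * class_balance)` positives, the rest
#' negatives with mechanisms drawn at random. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [generator_config()]
#' @return List of `structured_rna` records (positives first).
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  n_pos <- round(config$n_samples * config$class_balance)
  n_neg <- config$n_samples - n_pos
  pos <- lapply(seq_len(n_pos), function(i) {
    generate_hairpin(config, id = sprintf("pos%05d", i))
  })
  neg <- lapply(seq_len(n_neg), function(i) {
    generate_negative(config, id = sprintf("neg%05d", i))
  })
  c(pos, neg)
}

#' Generate a dataset labeled by a planted conjunctive rule
#'
#' The class is a known conjunction over structural features: positive
#' iff `pair_fraction > rule$pair_fraction` AND
#' `total_length > rule$total_length` AND
#' `max_asymmetric_bulge < rule$max_asym`. Positives satisfy all three
#' conditions with a safety margin; negatives are minimal-perturbation
#' decoys that violate exactly one condition (low pair fraction, short
#' molecule, or one large asymmetric bulge) while matching the positives
#' on the other two. Each rule condition is therefore individually
#' necessary to separate the classes, which makes recovering the planted
#' description a well-posed problem. Labels are assigned by evaluating
#' the rule on extracted features, never by construction bookkeeping.
#'
#' @param n number of records
#' @param seed RNG seed
#' @param rule named list with `pair_fraction`, `total_length`, `max_asym`
#' @param class_balance fraction of positives
#' @return List of labeled `structured_rna` records, shuffled.
#' @export
generate_planted_rule_dataset <- function(n, seed = 1L,
                                          rule = list(pair_fraction = 0.7,
                                                      total_length = 60,
                                                      max_asym = 5),
                                          class_balance = 0.5) {
  set.seed(seed)
  n_pos <- round(n * class_balance)
  kinds <- c(rep("pos", n_pos),
             rep(c("lowpair", "short", "bigbulge"), length.out = n - n_pos))
  rule_eval <- function(f) {
    as.integer(f$pair_fraction > rule$pair_fraction &
               f$total_length > rule$total_length &
               f$max_asymmetric_bulge < rule$max_asym)
  }
  draw <- function(kind) {
    base <- generator_config(
      n_samples = 1L,
      stem_length_range = if (kind == "short") c(14L, 24L) else c(28L, 45L),
      loop_length_range = if (kind == "short") c(3L, 8L) else c(3L, 15L),
      pair_fraction_range = if (kind == "lowpair") c(0.40, 0.64)
                            else c(0.76, 0.98),
      bulge_rate = 0.12, max_bulge_size = 3L, seed = 1L)
    for (i in 1:200) {
      r <- generate_hairpin(base, id = "cand")
      if (kind == "bigbulge") r <- insert_big_bulge(r, sizes = 6:8)
      f <- extract_features(r)
      ok <- switch(kind,
        pos = ,
        lowpair = ,
        bigbulge = f$total_length > rule$total_length + 4,
        short = f$total_length <= rule$total_length - 4)
      if (ok) return(r)
    }
    stop("planted-rule draw failed for kind '", kind, "'")
  }
  out <- lapply(seq_along(kinds), function(i) {
    r <- draw(kinds[i])
    f <- extract_features(r)
    r$label <- rule_eval(f)
    prefix <- if (r$label == 1L) "pos" else "neg"
    r$id <- sub("^cand", sprintf("%s%05d", prefix, i), r$id)
    r$id <- sub("mech=hairpin", paste0("kind=", kinds[i]), r$id)
    r
  })
  out[sample.int(length(out))]
}

# graft one large single-sided bulge into an existing stem at a random
# junction (used for the big-asymmetric-bulge decoys)
insert_big_bulge <- function(rna, sizes = 6:8) {
  pairs <- parse_pairs(rna$structure)
  np <- nrow(pairs)
  if (np < 2L) return(rna)
  j <- sample.int(np - 1L, 1L)
  size <- sample(sizes, 1L)
  side5 <- stats::runif(1) < 0.5
  at <- if (side5) pairs[j, 1L] else pairs[j + 1L, 2L]
  s <- strsplit(rna$sequence, "")[[1]]
  db <- strsplit(rna$structure, "")[[1]]
  ins <- random_nts(size)
  s <- append(s, ins, after = at)
  db <- append(db, rep(".", size), after = at)
  structured_rna(rna$id, paste(s, collapse = ""), paste(db, collapse = ""),
                 rna$label)
}

# ---- dataset I/O -----------------------------------------------------------

#' Write a dataset to disk
#'
#' Emits `sequences.fasta` (plain FASTA), `structures.dbn` (Vienna-style
#' `>id` / sequence / dot-bracket triplets) and `labels.tsv` (id, label).
#'
#' @param records list of `structured_rna`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- vapply(records, `[[`, "", "sequence")
  ids <- vapply(records, `[[`, "", "id")
  tryCatch({
    set <- Biostrings::RNAStringSet(seqs)
    names(set) <- ids
    Biostrings::writeXStringSet(set, file.path(dir, "sequences.fasta"))
    dbn <- unlist(lapply(records, function(r) {
      c(paste0(">", r$id), r$sequence, r$structure)
    }))
    writeLines(as.character(dbn), file.path(dir, "structures.dbn"))
    lab <- data.frame(id = ids,
                      label = vapply(records, `[[`, 0L, "label"))
    utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }, error = function(e) {
    stop("failed to write dataset to '", dir, "': ", conditionMessage(e))
  })
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `structures.dbn` and `labels.tsv`
#' @return List of `structured_rna` records in file order.
#' @export
read_dataset <- function(dir) {
  f <- file.path(dir, "structures.dbn")
  if (!file.exists(f)) stop("no structures.dbn found in '", dir, "'")
  lines <- readLines(f)
  if (!length(lines)) return(list())
  stopifnot(length(lines) %% 3L == 0L)
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                           header = TRUE, colClasses = c("character", "integer"))
  labels <- stats::setNames(lab$label, lab$id)
  idx <- seq(1L, length(lines), by = 3L)
  lapply(idx, function(k) {
    id <- sub("^>", "", lines[k])
    structured_rna(id, lines[k + 1L], lines[k + 2L],
                   label = labels[[id]])
  })
}

#' Labels of a record list as an integer vector
#' @param records list of `structured_rna`
#' @return Integer vector of class labels.
#' @export
dataset_labels <- function(records) {
  vapply(records, `[[`, 0L, "label")
}
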