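# Deterministic codec between a stem-loop record and its 100 x 25 bar
# image plus the length-100 bond-strength vector m.
#
# Geometry: column 1 holds the 5' terminus; the 5' arm runs left-to-right
# along the top edge and the 3' arm right-to-left along the bottom edge,
# so paired bases share a column. Unpaired stem bases face a 2-px black
# GAP bar on the opposite arm; the terminal loop wraps around the apex,
# first half (rounded up) on the top row. Bars grow from the outer edges
# inward.
#
# Bar-length table (the only quantitative choice the qualitative rules
# leave open): strong (Watson-Crick) bond 3 px; weak bond or bulge
# nucleotide 4 px plus 1 px per additional consecutive weak/none column
# in the run, capped at 12 px; GAP bars always 2 px; terminal-loop
# nucleotides 2 px. Lengths 2/3/>=4 therefore identify loop, strong and
# weak columns, which is what makes the codec exactly invertible.

#' @rdname encode_image
#' @format NULL
#' @export
COLOR_LEVELS <- c("A", "C", "G", "U", "GAP")

#' @rdname encode_image
#' @format NULL
#' @export
BAR_HEIGHTS <- c(0L, 2:12)

IMG_COLS <- 100L
IMG_ROWS <- 25L

#' Classify the bond between two aligned positions
#'
#' Strong iff the two nucleotides form a Watson-Crick pair (A-U or G-C);
#' any other paired combination (e.g. the G-U wobble) is weak; a gap or
#' an unpaired juxtaposition has no bond.
#'
#' @param top,bottom single letters in `A`, `C`, `G`, `U`, `GAP` (or `NA`)
#' @param paired whether the two positions are base-paired in the structure
#' @return `"strong"`, `"weak"` or `"none"`.
#' @examples
#' classify_bond("G", "C")  # strong
#' classify_bond("G", "U")  # weak
#' classify_bond("A", "GAP")  # none
#' @export
classify_bond <- function(top, bottom, paired = TRUE) {
  if (is.na(top) || is.na(bottom) || top == "GAP" || bottom == "GAP" || !paired) {
    return("none")
  }
  wc <- (top == "A" && bottom == "U") || (top == "U" && bottom == "A") ||
        (top == "G" && bottom == "C") || (top == "C" && bottom == "G")
  if (wc) "strong" else "weak"
}

#' Align the two arms of a stem-loop into image columns
#'
#' Walks the 5' arm left-to-right (top row) and the 3' arm right-to-left
#' (bottom row). Paired bases share a column; unpaired stem bases get a
#' `GAP` on the opposite row (5'-side runs emitted before 3'-side runs at
#' each junction); the terminal loop is split around the apex with the
#' first `ceiling(L/2)` bases on the top row and the remainder folding
#' back along the bottom row.
#'
#' @param rna a `structured_rna` whose structure is a single stem-loop
#' @return Data frame with one row per occupied column: `col`, `top`,
#'   `bottom` (letters, `"GAP"`, or `NA` for an absent bar), `bond`
#'   (strong/weak/none) and `role` (pair/bulge5/bulge3/loop).
#' @export
align_arms <- function(rna) {
  n <- nchar(rna$sequence)
  s <- strsplit(rna$sequence, "")[[1]]
  pairs <- parse_pairs(rna$structure)
  if (!is_single_stemloop(rna$structure)) {
    stop("structure of '", rna$id, "' is not a single stem-loop ",
         "(multiloops cannot be drawn as one hairpin image)")
  }
  partner <- integer(n)
  if (nrow(pairs)) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  cols <- list()
  push <- function(top, bottom, bond, role) {
    cols[[length(cols) + 1L]] <<- list(top = top, bottom = bottom,
                                       bond = bond, role = role)
  }
  if (!nrow(pairs)) {
    for (k in seq_len(n)) push(s[k], "GAP", "none", "bulge5")
  } else {
    inner <- pairs[nrow(pairs), ]
    a <- 1L; b <- n
    while (a <= inner[1L] || b >= inner[2L]) {
      if (a <= inner[1L] && partner[a] == b) {
        push(s[a], s[b], classify_bond(s[a], s[b]), "pair")
        a <- a + 1L; b <- b - 1L
      } else if (a <= inner[1L] && partner[a] == 0L) {
        push(s[a], "GAP", "none", "bulge5")
        a <- a + 1L
      } else if (b >= inner[2L] && partner[b] == 0L) {
        push("GAP", s[b], "none", "bulge3")
        b <- b - 1L
      } else {
        stop("internal error: inconsistent stem-loop walk")  # nocov
      }
    }
    loop <- seq(inner[1L] + 1L, inner[2L] - 1L)
    n_top <- ceiling(length(loop) / 2)
    c0 <- length(cols)
    for (t in seq_len(n_top)) push(s[loop[t]], NA_character_, "none", "loop")
    for (u in seq_len(length(loop) - n_top)) {
      cols[[c0 + n_top - u + 1L]]$bottom <- s[loop[n_top + u]]
    }
  }
  if (length(cols) > IMG_COLS) {
    stop("aligned structure of '", rna$id, "' needs ", length(cols),
         " columns; the image budget is ", IMG_COLS)
  }
  df <- data.frame(col = seq_along(cols),
                   top = vapply(cols, `[[`, "", "top"),
                   bottom = vapply(cols, function(x) {
                     if (is.null(x$bottom) || is.na(x$bottom)) NA_character_
                     else x$bottom
                   }, NA_character_),
                   bond = vapply(cols, `[[`, "", "bond"),
                   role = vapply(cols, `[[`, "", "role"),
                   stringsAsFactors = FALSE)
  df
}

# bar lengths for an alignment data frame, applying the run rule for
# consecutive weak/none stem columns
bar_lengths <- function(aln) {
  nc <- nrow(aln)
  top_len <- integer(nc); bot_len <- integer(nc)
  run <- 0L
  for (k in seq_len(nc)) {
    role <- aln$role[k]; bond <- aln$bond[k]
    if (role == "loop") {
      run <- 0L
      top_len[k] <- if (!is.na(aln$top[k])) 2L else 0L
      bot_len[k] <- if (!is.na(aln$bottom[k])) 2L else 0L
    } else if (bond == "strong") {
      run <- 0L
      top_len[k] <- 3L; bot_len[k] <- 3L
    } else {  # weak pair or bulge column
      run <- run + 1L
      len <- min(4L + run - 1L, 12L)
      top_len[k] <- if (identical(aln$top[k], "GAP")) 2L else len
      bot_len[k] <- if (identical(aln$bottom[k], "GAP")) 2L else len
    }
  }
  list(top = top_len, bottom = bot_len)
}

#' Bar table of an aligned record
#'
#' One row per bar (top and bottom of each occupied column) with its
#' color and pixel length; the tabular form consumed by the decoder
#' likelihood and the reconstruction metrics.
#'
#' @param rna a `structured_rna`
#' @return Data frame with `col`, `side` (`top`/`bottom`), `color`
#'   (factor over A/C/G/U/GAP) and `length` (0 for an absent bar).
#' @export
bar_table <- function(rna) {
  aln <- align_arms(rna)
  len <- bar_lengths(aln)
  data.frame(
    col = rep(aln$col, 2L),
    side = rep(c("top", "bottom"), each = nrow(aln)),
    color = factor(c(aln$top, aln$bottom), levels = COLOR_LEVELS),
    length = c(len$top, len$bottom),
    stringsAsFactors = FALSE
  )
}

#' Encode a stem-loop record as a bar image and bond vector
#'
#' @param rna a `structured_rna`
#' @return List with `image` (a 100 x 25 x 5 one-hot array, channels
#'   A/C/G/U/GAP, all-zero background) and `m` (length-100 binary vector,
#'   1 at columns whose bond is strong).
#' @examples
#' enc <- encode_image(structured_rna("toy", "GGGAAACCC", "(((...)))", 1L))
#' dim(enc$image)  # 100 25 5
#' sum(enc$m)      # 3 strong columns
#' @export
encode_image <- function(rna) {
  aln <- align_arms(rna)
  len <- bar_lengths(aln)
  img <- array(0, dim = c(IMG_COLS, IMG_ROWS, 5L))
  for (k in seq_len(nrow(aln))) {
    if (!is.na(aln$top[k]) && len$top[k] > 0L) {
      ch <- match(aln$top[k], COLOR_LEVELS)
      img[k, seq_len(len$top[k]), ch] <- 1
    }
    if (!is.na(aln$bottom[k]) && len$bottom[k] > 0L) {
      ch <- match(aln$bottom[k], COLOR_LEVELS)
      img[k, IMG_ROWS - seq_len(len$bottom[k]) + 1L, ch] <- 1
    }
  }
  m <- integer(IMG_COLS)
  m[aln$col[aln$bond == "strong"]] <- 1L
  list(image = img, m = m)
}

#' Read the bars back out of a bar image
#'
#' Validates the image invariants (one-hot pixels, bars attached to the
#' edges, single color per bar, at least one background row per column)
#' and returns the per-column bar table.
#'
#' @param img a 100 x 25 x 5 array
#' @return Data frame with `col`, `top_color`, `top_len`, `bottom_color`,
#'   `bottom_len` for every occupied column.
#' @export
bars_from_image <- function(img) {
  stopifnot(length(dim(img)) == 3L, all(dim(img) == c(IMG_COLS, IMG_ROWS, 5L)))
  hot <- apply(img != 0, c(1L, 2L), sum)
  bad <- which(hot > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("malformed image: multi-hot pixels at (col,row) ",
         paste(sprintf("(%d,%d)", bad[, 1L], bad[, 2L]), collapse = " "))
  }
  bar_color <- function(colv, rows) {
    if (!length(rows)) return(NA_character_)
    ch <- apply(colv[rows, , drop = FALSE] != 0, 1L, which)
    if (length(unique(ch)) != 1L) stop("malformed image: multicolor bar")
    COLOR_LEVELS[ch[1L]]
  }
  out <- vector("list", IMG_COLS)
  for (k in seq_len(IMG_COLS)) {
    colv <- img[k, , ]
    occ <- rowSums(colv != 0) > 0
    tl <- match(FALSE, occ, nomatch = IMG_ROWS + 1L) - 1L
    bl <- match(FALSE, rev(occ), nomatch = IMG_ROWS + 1L) - 1L
    if (tl + bl >= IMG_ROWS) {
      stop("malformed image: top and bottom bars overlap in column ", k)
    }
    if (any(occ[setdiff(which(occ), c(seq_len(tl), IMG_ROWS - seq_len(bl) + 1L))])) {
      stop("malformed image: floating pixels (bar not attached to an edge) ",
           "in column ", k)
    }
    top <- list(color = bar_color(colv, seq_len(tl)), len = tl)
    bot <- list(color = bar_color(colv, IMG_ROWS - seq_len(bl) + 1L), len = bl)
    if (top$len > 0L || bot$len > 0L) {
      out[[k]] <- data.frame(col = k, top_color = top$color, top_len = top$len,
                             bottom_color = bot$color, bottom_len = bot$len,
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(col = integer(0), top_color = character(0),
                      top_len = integer(0), bottom_color = character(0),
                      bottom_len = integer(0)))
  }
  do.call(rbind, out)
}

#' Render a bar table into an image array
#'
#' Inverse of [bars_from_image()]; used both by the codec and to render
#' discrete samples from the decoder.
#'
#' @param bars data frame as returned by [bars_from_image()]
#' @return A 100 x 25 x 5 array.
#' @export
bars_to_image <- function(bars) {
  img <- array(0, dim = c(IMG_COLS, IMG_ROWS, 5L))
  for (r in seq_len(nrow(bars))) {
    k <- bars$col[r]
    if (bars$top_len[r] > 0L && !is.na(bars$top_color[r])) {
      img[k, seq_len(bars$top_len[r]), match(bars$top_color[r], COLOR_LEVELS)] <- 1
    }
    if (bars$bottom_len[r] > 0L && !is.na(bars$bottom_color[r])) {
      img[k, IMG_ROWS - seq_len(bars$bottom_len[r]) + 1L,
          match(bars$bottom_color[r], COLOR_LEVELS)] <- 1
    }
  }
  img
}

#' Decode a bar image back into sequence and structure
#'
#' Exact inverse of [encode_image()] on its range: bar lengths identify
#' the column class (2 px nucleotide = terminal loop, 3 px = strong pair,
#' >= 4 px = weak pair or bulge, GAP opposite = bulge), from which the
#' sequence and dot-bracket are rebuilt.
#'
#' @param img a 100 x 25 x 5 array obeying the image invariants
#' @return A `structured_rna` (label `NA`).
#' @export
decode_image <- function(img) {
  bars <- bars_from_image(img)
  if (!nrow(bars)) return(structured_rna("decoded", "", ""))
  top_seq <- character(0); top_db <- character(0)
  bot_seq <- character(0); bot_db <- character(0)
  for (r in seq_len(nrow(bars))) {
    tc <- bars$top_color[r]; tl <- bars$top_len[r]
    bc <- bars$bottom_color[r]; bl <- bars$bottom_len[r]
    top_nt <- !is.na(tc) && tc != "GAP"
    bot_nt <- !is.na(bc) && bc != "GAP"
    paired <- top_nt && bot_nt && tl >= 3L && bl >= 3L
    if (top_nt) {
      top_seq <- c(top_seq, tc)
      top_db <- c(top_db, if (paired) "(" else ".")
    }
    if (bot_nt) {
      bot_seq <- c(bot_seq, bc)
      bot_db <- c(bot_db, if (paired) ")" else ".")
    }
  }
  # bottom row is read right-to-left to follow the strand around the apex
  seqs <- paste0(paste(top_seq, collapse = ""), paste(rev(bot_seq), collapse = ""))
  db <- paste0(paste(top_db, collapse = ""), paste(rev(bot_db), collapse = ""))
  structured_rna("decoded", seqs, db)
}

#' Recompute the bond vector from an image
#'
#' Independent of [encode_image()]'s bookkeeping: reads the bars and
#' marks columns whose two nucleotide bars are exactly 3 px (the strong
#' Watson-Crick signature).
#'
#' @param img a 100 x 25 x 5 array
#' @return Length-100 binary vector.
#' @export
bond_vector_from_image <- function(img) {
  bars <- bars_from_image(img)
  m <- integer(IMG_COLS)
  if (!nrow(bars)) return(m)
  strong <- !is.na(bars$top_color) & !is.na(bars$bottom_color) &
    bars$top_color != "GAP" & bars$bottom_color != "GAP" &
    bars$top_len == 3L & bars$bottom_len == 3L
  m[bars$col[strong]] <- 1L
  m
}
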