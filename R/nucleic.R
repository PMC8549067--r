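# Pet nucleic acids: sequence-based builders for single- and
# double-stranded DNA/RNA, double-strand detection, genome assembly around
# protein-binding sites, and expansion back to all-atom coordinates.
#
# Scale convention: the geometry table stores real-world Angstrom and
# degrees; pet builders multiply distances by 0.1.

#' Default nucleic-acid geometry
#'
#' The parameter set used to build nucleic acids and to assign force-field
#' equilibria, per helical form. Distances in Angstrom (real scale),
#' angles in degrees.
#'
#' @param form "bdna" or "arna".
#' @return named list of geometry parameters.
#' @export
na_geometry <- function(form = c("bdna", "arna")) {
  form <- match.arg(form)
  tab <- list(
    bdna = list(alpha = -46.85, beta = -146.06, gamma = 36.41,
                epsilon = 155, zeta = -95.18,
                rise_per_bp = 3.365, strand_shift = 0.5, twist_per_bp = 36,
                c1_axis_distance = 6.05, c1_sequential_distance = 4.95,
                c1_paired_distance = 10.8, angle_c1_c1_c1 = 153.795,
                angle_c1_paired_3prime = 54.581,
                angle_c1_paired_5prime = 100.424, dihedral_c1x4 = 24.907),
    arna = list(alpha = -73.728, beta = -173.666, gamma = 48.878,
                epsilon = -171.286, zeta = -66.929,
                rise_per_bp = 2.87768, strand_shift = -2, twist_per_bp = 36.787,
                c1_axis_distance = 7.318, c1_sequential_distance = 5.330,
                c1_paired_distance = 12.68, angle_c1_c1_c1 = 150.108,
                angle_c1_paired_3prime = 51.234,
                angle_c1_paired_5prime = 105.066, dihedral_c1x4 = 19.717))
  c(tab[[form]], list(form = form))
}

#' Parse dot-bracket secondary structure
#'
#' @param dotbracket string of '(', ')' and '.'.
#' @return integer vector: partner index per position, NA if unpaired.
#' @export
parse_dotbracket <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (!all(ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  partner
}

check_na_sequence <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "U")))
    stop("sequence contains non-ACGTU symbol: ",
         paste(unique(ch[!ch %in% c("A", "C", "G", "T", "U")]), collapse = ","))
  ch
}

#' Build a single-stranded pet nucleic acid from sequence
#'
#' One 0.5 A pet atom per nucleotide, positioned where the C1* atom of
#' the nucleotide will sit. Consecutive nucleotides are bonded; positions
#' marked as paired in the dot-bracket string receive an extra pairing
#' bond that preserves the secondary structure during simulation. The
#' conformation is a seeded self-avoiding random walk with the sequential
#' C1*-C1* distance as step length (pet scale) and a 0.4 A minimum
#' non-bonded separation; it is deliberately random, since the realistic
#' conformation emerges later from pet-world dynamics.
#'
#' @param seq nucleotide string (ACGT/U).
#' @param dotbracket optional dot-bracket string of the same length.
#' @param form "bdna" or "arna".
#' @param seed RNG seed for the walk.
#' @return a pet-kind `pet_object` with an `$na` description.
#' @export
build_pet_ss <- function(seq, dotbracket = NULL, form = c("bdna", "arna"),
                         seed = 0) {
  form <- match.arg(form)
  nt <- check_na_sequence(seq)
  n <- length(nt)
  geom <- na_geometry(form)
  pairing <- if (is.null(dotbracket)) rep(NA_integer_, n) else {
    if (nchar(dotbracket) != n)
      stop("dot-bracket length must match the sequence")
    parse_dotbracket(dotbracket)
  }
  step <- geom$c1_sequential_distance * 0.1
  min_sep <- 0.4
  xyz <- matrix(0, n, 3)
  # self-avoiding walk: step length from the sequential C1*-C1* distance;
  # bend angles scatter around the equilibrium C1*-C1*-C1* angle (a real
  # C1* chain is locally stiff), azimuths uniform
  with_seed(seed, {
    dirp <- c(1, 0, 0)
    if (n > 1) xyz[2, ] <- xyz[1, ] + step * dirp
    for (i in seq_len(n)[-(1:2)]) {
      cand <- NULL
      for (try in 1:200) {
        defl <- pi - deg2rad(geom$angle_c1_c1_c1 + stats::rnorm(1, 0, 10))
        az <- stats::runif(1, 0, 2 * pi)
        perp <- unit(cross3(dirp, if (abs(dirp[1]) < 0.9) c(1, 0, 0)
                            else c(0, 1, 0)))
        perp2 <- cross3(dirp, perp)
        d <- cos(defl) * dirp + sin(defl) * (cos(az) * perp +
                                               sin(az) * perp2)
        cand <- xyz[i - 1, ] + step * d
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) break
      }
      xyz[i, ] <- cand
      dirp <- d
    }
  })
  atoms <- atom_table(element = "O5", xyz = xyz, bfactor = 1,
                      elety = "C1P", resid = nt, resno = seq_len(n))
  bonds <- cbind(seq_len(n - 1), 2:n)
  pairs <- which(!is.na(pairing) & pairing > seq_len(n))
  if (length(pairs)) bonds <- rbind(bonds, cbind(pairing[pairs], pairs))
  obj <- molecular_object("pet_ss_na", atoms, bonds, kind = "pet")
  obj$na <- list(strandedness = "ss", sequence = paste(nt, collapse = ""),
                 form = form, pairing = pairing)
  obj
}

#' Build a double-stranded pet nucleic acid from sequence
#'
#' Double strands use a coarser model: each triplet of nucleotide pairs
#' becomes one 1.2 A main pet atom on the helical axis at the middle base
#' pair, plus a 0.1 A helper atom placed 1.2 A away from the main atom
#' (perpendicular to the axis) that rotates by three times the helical
#' twist between consecutive main atoms, tracking the backbone phase.
#'
#' @param seq base sequence of one strand (length >= 3).
#' @param form "bdna" or "arna".
#' @return a pet-kind `pet_object`; main and helper atoms alternate
#'   (main_k at row 2k-1, helper_k at row 2k).
#' @export
build_pet_ds <- function(seq, form = c("bdna", "arna")) {
  form <- match.arg(form)
  nt <- check_na_sequence(seq)
  n_bp <- length(nt)
  if (n_bp < 3) stop("double-stranded builder needs at least 3 base pairs")
  geom <- na_geometry(form)
  n_main <- ceiling(n_bp / 3)
  spacing <- 3 * geom$rise_per_bp * 0.1
  twist3 <- deg2rad(3 * geom$twist_per_bp)
  helper_off <- 1.2
  rows <- list(); bonds <- list()
  for (k in seq_len(n_main)) {
    z <- (k - 1) * spacing
    ang <- (k - 1) * twist3
    rows[[2 * k - 1]] <- c(0, 0, z)
    rows[[2 * k]] <- c(helper_off * cos(ang), helper_off * sin(ang), z)
    bonds[[length(bonds) + 1]] <- c(2 * k - 1, 2 * k)        # main-helper
    if (k > 1) bonds[[length(bonds) + 1]] <- c(2 * k - 3, 2 * k - 1)
  }
  xyz <- do.call(rbind, rows)
  atoms <- atom_table(element = rep(c("OC", "O1"), n_main), xyz = xyz,
                      bfactor = 1, elety = rep(c("AXM", "AXH"), n_main),
                      resid = "DSN", resno = rep(seq_len(n_main), each = 2))
  obj <- molecular_object("pet_ds_na", atoms, do.call(rbind, bonds),
                          kind = "pet")
  obj$na <- list(strandedness = "ds", sequence = paste(nt, collapse = ""),
                 form = form, n_bp = n_bp)
  obj
}

#' Detect double-stranded regions among pet nucleic strands
#'
#' Two strands qualify as a double strand when they are sequential in the
#' structure, have the same length, run anti-parallel, and every pair of
#' C1* positions (first of one strand against last of the other, and so
#' on) is closer than 1.2 A on the pet scale (12 A real scale).
#'
#' @param obj a nucleic `pet_object` whose atoms carry C1* positions (pet
#'   single-strand atoms, or all-atom C1*/C1' atoms).
#' @param scale "pet" or "real" (sets the 1.2 vs 12 A threshold).
#' @return list of pairings: each has `strand1`, `strand2` (atom index
#'   vectors, strand2 reported 3'->5' against strand1).
#' @export
detect_double_strand <- function(obj, scale = c("pet", "real")) {
  scale <- match.arg(scale)
  thresh <- if (scale == "pet") 1.2 else 12
  a <- obj$atoms
  is_c1 <- a$elety %in% c("C1P", "C1'", "C1*")
  idx <- which(if (any(is_c1)) is_c1 else rep(TRUE, nrow(a)))
  # strands = runs of consecutive residue numbers within one chain
  key <- a$chain[idx]
  brk <- c(TRUE, diff(a$resno[idx]) != 1 | key[-1] != key[-length(key)])
  strand_id <- cumsum(brk)
  strands <- split(idx, strand_id)
  xyz <- atom_xyz(a)
  out <- list()
  for (s in seq_len(length(strands) - 1)) {
    s1 <- strands[[s]]; s2 <- strands[[s + 1]]
    if (length(s1) != length(s2)) next
    s2r <- rev(s2)
    d <- sqrt(rowSums((xyz[s1, , drop = FALSE] - xyz[s2r, , drop = FALSE])^2))
    if (any(d >= thresh)) next
    if (length(s1) > 1) {
      d1 <- xyz[s1[length(s1)], ] - xyz[s1[1], ]
      d2 <- xyz[s2[length(s2)], ] - xyz[s2[1], ]
      if (sum(d1 * d2) >= 0) next  # parallel, not anti-parallel
    }
    out[[length(out) + 1]] <- list(strand1 = s1, strand2 = s2r)
  }
  out
}

#' Assemble a pet genome around protein-binding sites
#'
#' Scans the genome sequence for every occurrence of each binder's bound
#' subsequence (leftmost non-overlapping matches win; overlaps are
#' dropped with a warning). Each occurrence produces one copy of the
#' binding protein; the free stretches between sites are built with
#' [build_pet_ss()] and joined end-to-end with the binder fragments' pet
#' nucleic atoms into one connected chain.
#'
#' @param sequence genome nucleotide string.
#' @param binders list of binders; each a list with `site` (the bound
#'   subsequence) and `object` (a pet `pet_object` whose `$na_range`
#'   indexes its bound pet nucleic atoms in order).
#' @param form "bdna" or "arna".
#' @param seed RNG seed.
#' @return a `pet_scene`: object 1 is the assembled nucleic chain; each
#'   binder is one further object with one instance per occurrence. The
#'   chain object's `$genome` lists the match table.
#' @export
assemble_pet_genome <- function(sequence, binders = list(),
                                form = c("bdna", "arna"), seed = 0) {
  form <- match.arg(form)
  nt <- check_na_sequence(sequence)
  n <- length(nt)
  seqstr <- paste(nt, collapse = "")
  # leftmost non-overlapping site matches across all binders
  matches <- list()
  occupied <- rep(FALSE, n)
  for (b in seq_along(binders)) {
    site <- toupper(binders[[b]]$site)
    hits <- gregexpr(site, seqstr, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits) {
      span <- h:(h + nchar(site) - 1)
      if (any(occupied[span])) {
        warning("overlapping binding site at position ", h, " dropped")
        next
      }
      occupied[span] <- TRUE
      matches[[length(matches) + 1]] <- list(binder = b, start = h,
                                             end = h + nchar(site) - 1)
    }
  }
  ord <- order(vapply(matches, `[[`, 1, "start"))
  matches <- matches[ord]
  geom <- na_geometry(form)
  step <- geom$c1_sequential_distance * 0.1
  # build the chain: free stretches via the ss walk, binder fragments as
  # rigid pieces translated to continue from the previous chain end
  atoms <- NULL; bonds <- NULL; binder_instances <- vector("list", length(binders))
  cursor <- c(0, 0, 0); prev_end <- 0L; pos <- 0L
  add_piece <- function(piece_xyz, piece_atoms) {
    off <- nrow(atoms %||% data.frame())
    if (!is.null(atoms) && nrow(piece_atoms) > 0)
      bonds <<- rbind(bonds, c(off, off + 1L))  # join to previous piece
    atoms <<- rbind(atoms, piece_atoms)
    off
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  with_seed(seed, {
    boundaries <- c(vapply(matches, `[[`, 1, "start") - 1, n)
    site_spans <- matches
    cur <- 1L
    for (k in seq_len(length(matches) + 1)) {
      free_end <- if (k <= length(matches)) matches[[k]]$start - 1 else n
      if (free_end >= cur) {
        sub <- substr(seqstr, cur, free_end)
        piece <- build_pet_ss(sub, form = form,
                              seed = sample.int(2^30, 1))
        pxyz <- sweep(atom_xyz(piece$atoms), 2,
                      cursor + c(step, 0, 0) - atom_xyz(piece$atoms)[1, ], "+")
        pa <- piece$atoms; pa[, c("x", "y", "z")] <- pxyz
        off <- nrow(atoms %||% pa[0, ])
        if (!is.null(atoms)) bonds <- rbind(bonds, c(off, off + 1L))
        atoms <- rbind(atoms, pa)
        bonds <- rbind(bonds, piece$bonds + off)
        cursor <- pxyz[nrow(pxyz), ]
      }
      if (k <= length(matches)) {
        m <- matches[[k]]
        bobj <- binders[[m$binder]]$object
        rng <- bobj$na_range
        if (is.null(rng)) stop("binder object lacks $na_range")
        frag <- bobj$atoms[rng, , drop = FALSE]
        shift <- cursor + c(step, 0, 0) - atom_xyz(frag)[1, ]
        fa <- frag
        fa[, c("x", "y", "z")] <- sweep(atom_xyz(frag), 2, shift, "+")
        off <- nrow(atoms %||% fa[0, ])
        if (!is.null(atoms)) bonds <- rbind(bonds, c(off, off + 1L))
        atoms <- rbind(atoms, fa)
        if (length(rng) > 1)
          bonds <- rbind(bonds, cbind(off + seq_len(length(rng) - 1),
                                      off + 2:length(rng)))
        cursor <- atom_xyz(fa)[nrow(fa), ]
        binder_instances[[m$binder]] <-
          c(binder_instances[[m$binder]],
            list(instance_transform(diag(3), shift)))
        cur <- m$end + 1L
      } else cur <- free_end + 1L
    }
  })
  atoms$eleno <- seq_len(nrow(atoms))
  chain <- molecular_object("pet_genome", atoms,
                            matrix(as.integer(bonds), ncol = 2), kind = "pet")
  chain$genome <- list(sequence = seqstr, matches = matches)
  objs <- list(chain); inst <- list(list(instance_transform()))
  for (b in seq_along(binders)) {
    if (length(binder_instances[[b]]) == 0) next
    objs[[length(objs) + 1]] <- binders[[b]]$object
    inst[[length(inst) + 1]] <- binder_instances[[b]]
  }
  scene_model(objs, inst, scale = "pet")
}
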