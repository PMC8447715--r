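# Alpha-helix assignment, helix-dipole stabilization scoring and residue
# composition metrics.  Charged residues near helix termini interact with the
# helix macrodipole: a positive charge (Lys/Arg/His) in the last three
# residues stabilizes, a negative charge (Glu/Asp) there destabilizes, and
# vice versa at the N-terminus.

.positive_set <- c("LYS", "ARG", "HIS")
.negative_set <- c("GLU", "ASP")

#' Assign alpha-helices
#'
#' In `"records"` mode the HELIX annotations parsed from the PDB file are
#' returned.  In `"dihedral"` mode helices are maximal runs of at least four
#' consecutive residues with phi in \[-100, -30\] and psi in \[-80, -5\]
#' degrees (computed from backbone N/CA/C atoms); this is the fallback when a
#' model carries no HELIX records.
#'
#' @param model A `structure_model`.
#' @param source `"records"` (default) or `"dihedral"`.
#' @param phi_range,psi_range Dihedral windows (degrees) for dihedral mode.
#' @return Data frame with columns `chain`, `start`, `end`, `length`.
#' @export
assign_helices <- function(model, source = c("records", "dihedral"),
                           phi_range = c(-100, -30),
                           psi_range = c(-80, -5)) {
  source <- match.arg(source)
  if (source == "records") {
    h <- model$helix
    if (nrow(h) == 0L) {
      stop("model has no HELIX records; rerun with source = \"dihedral\"")
    }
    h$length <- h$end - h$start + 1L
    return(h)
  }
  res <- .residues(model)
  info <- res$info
  a <- model$atoms
  bb <- function(i, nm) {
    rows <- res$atoms[[i]]
    j <- rows[a$name[rows] == nm]
    if (length(j) == 0L) return(NULL)
    as.numeric(a[j[1L], c("x", "y", "z")])
  }
  n <- nrow(info)
  helical <- rep(FALSE, n)
  in_rng <- function(x, rng) !is.null(x) && x >= rng[1L] && x <= rng[2L]
  for (i in seq_len(n)) {
    prev_ok <- i > 1L && info$chain[i - 1L] == info$chain[i] &&
      info$resno[i - 1L] == info$resno[i] - 1L
    next_ok <- i < n && info$chain[i + 1L] == info$chain[i] &&
      info$resno[i + 1L] == info$resno[i] + 1L
    ni <- bb(i, "N"); cai <- bb(i, "CA"); ci <- bb(i, "C")
    if (is.null(ni) || is.null(cai) || is.null(ci)) next
    phi <- psi <- NULL
    if (prev_ok && !is.null(bb(i - 1L, "C"))) {
      phi <- .dihedral(bb(i - 1L, "C"), ni, cai, ci)
    }
    if (next_ok && !is.null(bb(i + 1L, "N"))) {
      psi <- .dihedral(ni, cai, ci, bb(i + 1L, "N"))
    }
    # chain-terminal residues have only one defined dihedral; they join the
    # helix when that dihedral qualifies
    if (is.null(phi) && is.null(psi)) next
    helical[i] <- (is.null(phi) || in_rng(phi, phi_range)) &&
      (is.null(psi) || in_rng(psi, psi_range))
  }
  runs <- rle(helical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= 4L
  out <- data.frame(chain = info$chain[starts[keep]],
                    start = info$resno[starts[keep]],
                    end = info$resno[ends[keep]],
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out
}

#' Score helix-dipole stabilization
#'
#' Inspects the first three and last three residues of each helix.  At the
#' C-terminus a positive residue (Lys/Arg/His) counts as stabilizing and a
#' negative residue (Glu/Asp) as destabilizing; at the N-terminus the roles
#' are reversed.  A helix is flagged stabilized when its stabilizing count
#' exceeds its destabilizing count.  For helices shorter than six residues
#' the two windows overlap and a residue is counted once per window it falls
#' in (with a warning).
#'
#' @param model A `structure_model`.
#' @param helices Helix annotation data frame from [assign_helices()].
#' @param window Number of residues inspected at each terminus (default 3).
#' @return List of class `dipole_score` with elements `per_helix` (one row
#'   per helix with the four counts, `net` and `stabilized`) and `totals`
#'   (summed counts, total `net`, and `n_stabilized`).
#' @export
score_helix_dipoles <- function(model, helices, window = 3L) {
  res <- .residues(model)
  info <- res$info
  ph <- lapply(seq_len(nrow(helices)), function(i) {
    h <- helices[i, ]
    in_h <- info$chain == h$chain & info$resno >= h$start &
      info$resno <= h$end
    seqres <- info[in_h, , drop = FALSE]
    seqres <- seqres[order(seqres$resno), , drop = FALSE]
    m <- nrow(seqres)
    if (m == 0L) {
      stop(sprintf("helix %s %d-%d has no residues in the model",
                   h$chain, h$start, h$end))
    }
    if (m < 2L * window) {
      warning(sprintf(
        "helix %s %d-%d shorter than %d residues: terminal windows overlap",
        h$chain, h$start, h$end, 2L * window))
    }
    n_win <- seqres$resname[seq_len(min(window, m))]
    c_win <- seqres$resname[seq.int(max(1L, m - window + 1L), m)]
    data.frame(
      chain = h$chain, start = h$start, end = h$end,
      n_term_stabilizing = sum(n_win %in% .negative_set),
      n_term_destabilizing = sum(n_win %in% .positive_set),
      c_term_stabilizing = sum(c_win %in% .positive_set),
      c_term_destabilizing = sum(c_win %in% .negative_set),
      stringsAsFactors = FALSE
    )
  })
  per_helix <- do.call(rbind, ph)
  if (is.null(per_helix)) {
    per_helix <- data.frame(chain = character(), start = integer(),
                            end = integer(),
                            n_term_stabilizing = integer(),
                            n_term_destabilizing = integer(),
                            c_term_stabilizing = integer(),
                            c_term_destabilizing = integer())
  }
  per_helix$net <- with(per_helix,
                        n_term_stabilizing + c_term_stabilizing -
                          n_term_destabilizing - c_term_destabilizing)
  per_helix$stabilized <-
    with(per_helix, n_term_stabilizing + c_term_stabilizing >
           n_term_destabilizing + c_term_destabilizing)
  totals <- list(
    n_term_stabilizing = sum(per_helix$n_term_stabilizing),
    n_term_destabilizing = sum(per_helix$n_term_destabilizing),
    c_term_stabilizing = sum(per_helix$c_term_stabilizing),
    c_term_destabilizing = sum(per_helix$c_term_destabilizing),
    net = sum(per_helix$net),
    n_stabilized = sum(per_helix$stabilized)
  )
  structure(list(per_helix = per_helix, totals = totals),
            class = "dipole_score")
}

#' @export
print.dipole_score <- function(x, ...) {
  cat(sprintf(
    "<dipole_score> %d helices, %d stabilized, net %+d\n",
    nrow(x$per_helix), x$totals$n_stabilized, x$totals$net))
  invisible(x)
}

#' Proline/glycine ratio
#'
#' count(Pro) / count(Gly) over polymer residues.  An increased Pro/Gly
#' ratio (rigidifying prolines, fewer flexible glycines) is a classic
#' thermostability indicator.
#'
#' @param model A `structure_model`.
#' @return Numeric ratio; `NA` with a warning when the model contains no
#'   glycine.
#' @export
pro_gly_ratio <- function(model) {
  info <- .residues(model)$info
  n_gly <- sum(info$resname == "GLY")
  if (n_gly == 0L) {
    warning("no glycine residues: Pro/Gly ratio undefined")
    return(NA_real_)
  }
  sum(info$resname == "PRO") / n_gly
}
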