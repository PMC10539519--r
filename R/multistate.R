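GAS_CONSTANT_KCAL <- 1.9872e-3   # kcal / (mol K)

#' Enumerate the designed sequence space
#'
#' Lexicographic enumeration of all amino-acid combinations at the
#' designed positions. For 4 positions and the 19-letter designable
#' alphabet this is 19^4 = 130,321 sequences.
#'
#' @param n_positions number of designed positions.
#' @param alphabet character vector of 1-letter amino-acid codes
#'   (default: the 19 designable types, proline excluded).
#' @return list with `count`, `alphabet`, `get(i)` (i-th sequence,
#'   1-based, as a string) and `materialize(limit)` (character vector;
#'   errors if count exceeds `limit`).
#' @export
enumerate_sequences <- function(n_positions,
                                alphabet = sort(unname(AA1[DESIGN_ALPHABET]))) {
  stopifnot(length(alphabet) >= 1, n_positions >= 1)
  alphabet <- sort(alphabet)
  count <- length(alphabet)^n_positions
  get <- function(i) {
    stopifnot(i >= 1, i <= count)
    i <- i - 1
    out <- character(n_positions)
    for (p in n_positions:1) {
      out[p] <- alphabet[(i %% length(alphabet)) + 1]
      i <- i %/% length(alphabet)
    }
    paste(out, collapse = "")
  }
  materialize <- function(limit = 1e6) {
    if (count > limit)
      stop("sequence space (", count, ") exceeds limit (", limit, ")")
    grid <- expand.grid(rev(rep(list(alphabet), n_positions)),
                        stringsAsFactors = FALSE)[, n_positions:1,
                                                  drop = FALSE]
    apply(grid, 1, paste, collapse = "")
  }
  list(count = count, alphabet = alphabet, get = get,
       materialize = materialize)
}

#' Boltzmann-weighted average of member energies
#'
#' `E_bar = sum_b E_b w_b` with `w_b = exp(-E_b/RT) / sum exp(-E_b/RT)`,
#' computed with log-sum-exp stabilization. Lower-energy members get
#' more weight, so `min(E) <= E_bar <= mean(E)`.
#'
#' @param e numeric vector of member energies, kcal/mol.
#' @param temperature kelvin (default 300).
#' @return kcal/mol.
#' @export
boltzmann_average <- function(e, temperature = 300) {
  stopifnot(length(e) >= 1, temperature > 0)
  x <- -e / (GAS_CONSTANT_KCAL * temperature)
  w <- exp(x - max(x))
  sum(e * w) / sum(w)
}

#' Boltzmann-weighted state energy of a sequence on an ensemble
#'
#' Optimizes the sequence's rotamers on every ensemble member with
#' [faster_optimize()], then Boltzmann-weights the per-member optimized
#' energies at the given temperature.
#'
#' @param seq sequence string (1-letter codes, one per design position).
#' @param member_matrices list of [energy_matrices()], one per ensemble
#'   member.
#' @param temperature kelvin (default 300).
#' @return list: `energy` (kcal/mol), `member_energies`, `clash_flag`
#'   (TRUE when every member is at the clash cap).
#' @export
state_energy <- function(seq, member_matrices, temperature = 300) {
  aa3 <- AA3[strsplit(seq, "")[[1]]]
  if (anyNA(aa3)) stop("unknown amino-acid letter in sequence ", seq)
  eb <- vapply(member_matrices, function(m)
    faster_optimize(m, seq = unname(aa3))$energy, numeric(1))
  nflag <- sum(eb >= CLASH_CAP)
  list(energy = boltzmann_average(eb, temperature), member_energies = eb,
       clash_flag = nflag == length(eb))
}

#' Sequence design records
#'
#' @param sequence character vector of sequence strings.
#' @param e_closed,e_open Boltzmann-weighted state energies, kcal/mol.
#' @return data.frame with `sequence`, `E_closed`, `E_open`, `delta_e`
#'   (`= E_closed - E_open`).
#' @export
design_records <- function(sequence, e_closed, e_open) {
  data.frame(sequence = sequence, E_closed = e_closed, E_open = e_open,
             delta_e = e_closed - e_open, stringsAsFactors = FALSE)
}

#' Percentile filter and Delta-E ranking
#'
#' Discards sequences whose `E_closed` or `E_open` is above the given
#' percentile of the respective column (high-energy outliers would make
#' Delta E artificially favorable), then sorts the survivors by Delta E:
#' ascending for the closed objective (most closed-stabilizing first),
#' descending for the open objective.
#'
#' @param records [design_records()] data.frame.
#' @param percentile filter percentile (default 75).
#' @param objective `"closed"` or `"open"`.
#' @return filtered, sorted data.frame.
#' @export
rank_by_delta_e <- function(records, percentile = 75,
                            objective = c("closed", "open")) {
  objective <- match.arg(objective)
  if (nrow(records) < 1) stop("no records")
  qc <- quantile(records$E_closed, percentile / 100, names = FALSE)
  qo <- quantile(records$E_open, percentile / 100, names = FALSE)
  keep <- records$E_closed <= qc & records$E_open <= qo
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("percentile filter removed all records")
  ord <- order(out$delta_e, out$sequence,
               decreasing = c(objective == "open", FALSE), method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combinatorial library design (CLEARSS-style)
#'
#' Selects one amino-acid set per position so that the combinatorial
#' library size (product of set sizes) falls within `target +/- tol`.
#' Per-position amino-acid weights are Boltzmann factors over Delta E
#' (`exp(-Delta E / T_sel)` for the closed objective, sign reversed for
#' open), normalized to probabilities. Every feasible size configuration
#' is enumerated; for each, the top-n amino acids by probability are
#' chosen at each position and the configuration score is the summed
#' probability mass of the chosen sets. The highest-scoring library is
#' returned, ties broken by smaller size then lexicographic sets.
#'
#' @param records [design_records()] data.frame.
#' @param target target library size (default 20).
#' @param tol tolerance (default 4).
#' @param t_sel selection temperature on the kcal/mol scale (default 1).
#' @param objective `"closed"` or `"open"`.
#' @return object of class `LibraryDesign`: list with `sets` (per-position
#'   character vectors), `size`, `score`, `target`, `tol`,
#'   `probabilities` (per-position named vectors).
#' @export
clearss_design <- function(records, target = 20, tol = 4, t_sel = 1,
                           objective = c("closed", "open")) {
  objective <- match.arg(objective)
  sgn <- if (objective == "closed") 1 else -1
  k <- nchar(records$sequence[1])
  letters_by_pos <- lapply(seq_len(k), function(i)
    substr(records$sequence, i, i))
  probs <- vector("list", k)
  for (i in seq_len(k)) {
    x <- -sgn * records$delta_e / t_sel
    x <- x - max(x)                       # overflow guard
    w <- tapply(exp(x), letters_by_pos[[i]], sum)
    p <- w / sum(w)
    # deterministic order: probability descending, then alphabetical
    probs[[i]] <- p[order(-p, names(p), method = "radix")]
  }
  nmax <- vapply(probs, length, integer(1))
  configs <- enumerate_size_configs(nmax, target - tol, target + tol)
  if (nrow(configs) == 0)
    stop("no feasible size configuration for target ", target, " +/- ", tol)
  best <- NULL
  for (r in seq_len(nrow(configs))) {
    n <- as.integer(configs[r, ])
    sets <- lapply(seq_len(k), function(i) sort(names(probs[[i]])[seq_len(n[i])]))
    score <- sum(vapply(seq_len(k), function(i)
      sum(probs[[i]][seq_len(n[i])]), numeric(1)))
    size <- prod(n)
    cand <- list(sets = sets, size = size, score = score)
    if (is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (size < best$size ||
          (size == best$size &&
           paste(unlist(sets), collapse = "") <
             paste(unlist(best$sets), collapse = "")))))
      best <- cand
  }
  structure(list(sets = best$sets, size = best$size, score = best$score,
                 target = target, tol = tol, objective = objective,
                 probabilities = probs), class = "LibraryDesign")
}

# all (n_1..n_k) with 1 <= n_i <= nmax_i and product within [lo, hi]
enumerate_size_configs <- function(nmax, lo, hi) {
  k <- length(nmax)
  res <- list()
  rec <- function(i, cur, prodv) {
    if (prodv > hi) return()
    if (i > k) {
      if (prodv >= lo) res[[length(res) + 1]] <<- cur
      return()
    }
    # remaining positions can multiply by at most prod(nmax[i:k])
    maxrest <- prod(nmax[i:k])
    if (prodv * maxrest < lo) return()
    for (n in seq_len(nmax[i])) rec(i + 1, c(cur, n), prodv * n)
  }
  rec(1, integer(0), 1)
  if (length(res) == 0) return(matrix(integer(0), 0, k))
  do.call(rbind, res)
}

#' @export
print.LibraryDesign <- function(x, ...) {
  cat(sprintf("LibraryDesign (%s objective): %d sequences (target %d +/- %d), score %.4f\n",
              x$objective, x$size, x$target, x$tol, x$score))
  for (i in seq_along(x$sets))
    cat(sprintf("  position %d: {%s}\n", i, paste(x$sets[[i]], collapse = ", ")))
  invisible(x)
}

#' Expand a library design into its member sequences
#' @param lib [clearss_design()] result.
#' @return character vector of sequence strings (lexicographic).
#' @export
expand_library <- function(lib) {
  grid <- expand.grid(rev(lib$sets), stringsAsFactors = FALSE)
  out <- apply(grid[, rev(seq_along(lib$sets)), drop = FALSE], 1, paste,
               collapse = "")
  sort(out)
}

#' Full multistate design pipeline on two ensembles
#'
#' Builds design energy matrices for every member of the open and
#' closed ensembles, computes Boltzmann-weighted state energies for all
#' sequences in the design space, applies the percentile filter and
#' Delta-E ranking, and designs a combinatorial library.
#'
#' @param open_ens,closed_ens [generate_ensemble()] results.
#' @param positions data.frame with `chain`, `resno`.
#' @param alphabet candidate amino acids (3-letter codes).
#' @param lib rotamer library.
#' @param ff force-field tables.
#' @param temperature kelvin for the Boltzmann weighting (default 300).
#' @param percentile filter percentile (default 75).
#' @param target,tol library size target (default 20 +/- 4).
#' @param t_sel selection temperature (default 1 kcal/mol).
#' @param objective `"closed"` (default) or `"open"`.
#' @return list with `records` (all sequences), `ranked` (filtered,
#'   sorted), `library` ([clearss_design()] result).
#' @export
design_pipeline <- function(open_ens, closed_ens, positions,
                            alphabet = setdiff(DESIGN_ALPHABET, "GLY"),
                            lib = load_rotamer_library(),
                            ff = load_ff_tables(), temperature = 300,
                            percentile = 75, target = 20, tol = 4,
                            t_sel = 1, objective = "closed") {
  m_open <- lapply(open_ens$members, build_energy_matrices,
                   positions = positions, lib = lib, alphabet = alphabet,
                   ff = ff)
  m_closed <- lapply(closed_ens$members, build_energy_matrices,
                     positions = positions, lib = lib, alphabet = alphabet,
                     ff = ff)
  seqs <- enumerate_sequences(nrow(positions),
                              alphabet = sort(unname(AA1[alphabet])))
  all_seqs <- seqs$materialize()
  e_open <- vapply(all_seqs, function(s)
    state_energy(s, m_open, temperature)$energy, numeric(1))
  e_closed <- vapply(all_seqs, function(s)
    state_energy(s, m_closed, temperature)$energy, numeric(1))
  records <- design_records(all_seqs, e_closed, e_open)
  ranked <- rank_by_delta_e(records, percentile, objective)
  libdes <- clearss_design(ranked, target = target, tol = tol,
                           t_sel = t_sel, objective = objective)
  list(records = records, ranked = ranked, library = libdes)
}
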