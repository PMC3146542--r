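# The order/disorder free energy.
#
# Each residue is either fully ordered or fully disordered. Ordered
# residues contribute their pairwise interaction energy with all other
# ordered residues and no entropy. Disordered residues contribute no
# interaction energy; a disordered run touching either terminus (a "tail")
# earns a per-residue entropy credit E_d, and a disordered internal run of
# length L (a "loop") earns a per-loop credit beta * log(L / L0). The total
# free energy of an assignment is
#
#     F = E - sum_tail_residues E_d - sum_loops beta * log(L / L0)
#
# with temperature absorbed into E_d and beta (both are expressed directly
# in the energy units of the interaction matrix).

#' Free-energy model parameters
#'
#' @param E_d Per-residue entropy credit for disordered terminal residues
#'   (energy units). Default 2.0, the value at which terminal-disorder
#'   recovery is most accurate.
#' @param beta Scale of the internal-loop entropy term. Default 1.5.
#' @param L0 Reference loop length for the internal-loop entropy. Default
#'   0.3 (so `log(L / L0) > 0` for every admissible loop).
#' @param min_loop_len Minimum length of a disordered internal run.
#'   Default 4.
#' @param block Number of consecutive residues flipped at a time by the
#'   greedy internal search. Default 4.
#' @param max_stretches Maximum number of disordered stretches in the
#'   terminal-enumeration search (2: one tail per terminus).
#' @return An object of class `fe_params`.
#' @export
fe_params <- function(E_d = 2.0, beta = 1.5, L0 = 0.3, min_loop_len = 4L,
                      block = 4L, max_stretches = 2L) {
  if (E_d <= 0 || beta <= 0 || L0 <= 0) {
    abort("E_d, beta and L0 must be positive")
  }
  min_loop_len <- as.integer(min_loop_len)
  if (min_loop_len < 1L) abort("min_loop_len must be >= 1")
  if (min_loop_len / L0 <= 1) {
    abort("L0 must be smaller than min_loop_len (loop credit must be > 0)")
  }
  structure(
    list(E_d = E_d, beta = beta, L0 = L0, min_loop_len = min_loop_len,
         block = as.integer(block), max_stretches = as.integer(max_stretches)),
    class = "fe_params"
  )
}

# Maximal disordered runs of an ordered/disordered vector, classified as
# tails (touching position 1 or n) or internal loops.
disorder_runs <- function(ordered) {
  n <- length(ordered)
  r <- rle(ordered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dis <- which(!r$values)
  if (length(dis) == 0L) {
    return(list(tails = integer(), loops = integer(),
                starts = integer(), is_tail = logical()))
  }
  s <- starts[dis]; e <- ends[dis]; len <- r$lengths[dis]
  is_tail <- s == 1L | e == n
  list(tails = len[is_tail], loops = len[!is_tail],
       starts = s, is_tail = is_tail)
}

entropy_terms <- function(ordered, params) {
  runs <- disorder_runs(ordered)
  if (any(runs$loops < params$min_loop_len)) {
    abort(sprintf(
      "internal disordered run shorter than min_loop_len = %d",
      params$min_loop_len))
  }
  list(
    tail_term = params$E_d * sum(runs$tails),
    loop_term = params$beta * sum(log(runs$loops / params$L0))
  )
}

new_assignment <- function(ordered, E, tail_term, loop_term) {
  structure(
    list(ordered = ordered,
         breakdown = list(E = E, tail_term = tail_term,
                          loop_term = loop_term,
                          F = E - tail_term - loop_term)),
    class = "disorder_assignment"
  )
}

#' Free energy of an order/disorder assignment
#'
#' Evaluates `F = E - tail_term - loop_term` for a given assignment, where
#' `E` sums the interaction matrix over pairs of ordered residues,
#' `tail_term = E_d * (number of disordered residues in terminal runs)` and
#' `loop_term = sum over internal runs of beta * log(L / L0)`.
#'
#' @param m An `interaction_matrix`.
#' @param ordered Logical vector (`TRUE` = ordered), length `m$n`. Internal
#'   disordered runs must be at least `min_loop_len` long.
#' @param params An [fe_params()] object.
#' @return A `disorder_assignment`: the `ordered` vector plus a `breakdown`
#'   list `(E, tail_term, loop_term, F)` satisfying
#'   `F = E - tail_term - loop_term` exactly.
#' @export
free_energy <- function(m, ordered, params = fe_params()) {
  stopifnot(inherits(m, "interaction_matrix"))
  ordered <- as.logical(ordered)
  if (length(ordered) != m$n) abort("assignment length must equal m$n")
  ent <- entropy_terms(ordered, params)
  keep <- which(ordered)
  E <- sum(m$e_attr[keep, keep] + m$e_rep[keep, keep]) / 2
  new_assignment(ordered, E, ent$tail_term, ent$loop_term)
}

#' @export
print.disorder_assignment <- function(x, ...) {
  b <- x$breakdown
  cat("<disorder_assignment> ", sum(!x$ordered), "/", length(x$ordered),
      " residues disordered\n", sep = "")
  cat(sprintf("  E = %.4f, tail = %.4f, loop = %.4f, F = %.4f\n",
              b$E, b$tail_term, b$loop_term, b$F))
  invisible(x)
}

n_tail_lengths <- function(ordered) {
  n <- length(ordered)
  n_tail <- if (!ordered[1]) which.max(ordered) - 1L else 0L
  if (all(!ordered)) n_tail <- n
  c_tail <- if (!ordered[n]) which.max(rev(ordered)) - 1L else 0L
  if (all(!ordered)) c_tail <- 0L
  c(n_tail = n_tail, c_tail = c_tail)
}

# TRUE if `a` beats `b` under the deterministic tie cascade:
# lower F, then fewer disordered residues, then lexicographically greatest
# ordered vector (for tail-only assignments this selects the smaller
# N-terminal tail).
better_assignment <- function(Fa, orda, Fb, ordb) {
  if (Fa != Fb) return(Fa < Fb)
  da <- sum(!orda); db <- sum(!ordb)
  if (da != db) return(da < db)
  d <- which(orda != ordb)
  if (length(d) == 0L) return(FALSE)
  orda[d[1L]] # TRUE: a is ordered earlier at the first difference
}

#' Exhaustive terminal-tail search
#'
#' Enumerates every assignment with at most two disordered stretches, one
#' at each terminus: all `(a, b)` with N-tail length `a >= 0`, C-tail
#' length `b >= 0` and `a + b < n` (at least one residue stays ordered).
#' Returns the assignment minimizing `F`; ties are broken toward fewer
#' disordered residues, then toward the smaller N-tail.
#'
#' @param m An `interaction_matrix` with `n >= 2`.
#' @param params An [fe_params()] object.
#' @return The optimal `disorder_assignment`.
#' @export
enumerate_terminal <- function(m, params = fe_params()) {
  stopifnot(inherits(m, "interaction_matrix"))
  n <- m$n
  if (n < 2L) abort("enumerate_terminal needs n >= 2")
  M <- m$e_attr + m$e_rep
  # 2-d cumulative sum: block sums of M over [l..r] x [l..r] in O(1)
  C <- apply(apply(M, 2, cumsum), 1, cumsum) # C[j, i] = sum M[1:i, 1:j]
  C <- t(C)
  block_sum <- function(l, r) {
    if (l > r) return(0)
    s <- C[r, r]
    if (l > 1L) s <- s - C[l - 1L, r] - C[r, l - 1L] + C[l - 1L, l - 1L]
    s
  }
  best <- NULL
  for (a in 0:(n - 1L)) {
    for (b in 0:(n - 1L - a)) {
      E <- block_sum(a + 1L, n - b) / 2
      F_ <- E - params$E_d * (a + b)
      ordered <- rep(TRUE, n)
      if (a > 0L) ordered[seq_len(a)] <- FALSE
      if (b > 0L) ordered[(n - b + 1L):n] <- FALSE
      if (is.null(best) ||
          better_assignment(F_, ordered, best$F_, best$ordered)) {
        best <- list(F_ = F_, ordered = ordered)
      }
    }
  }
  free_energy(m, best$ordered, params)
}

#' Greedy internal-loop search
#'
#' Starts from the all-ordered assignment and repeatedly flips blocks of
#' `params$block` consecutive currently-ordered residues to disordered,
#' evaluating every offset, committing the single flip that lowers `F` the
#' most, and stopping when no flip lowers it. Flipped blocks adjacent to an
#' existing disordered run merge with it; merged runs touching a terminus
#' are scored as tails, all others as internal loops (which must respect
#' `min_loop_len`). Only order-to-disorder flips are made, and at least one
#' residue always stays ordered.
#'
#' @param m An `interaction_matrix` with `n >= params$block`.
#' @param params An [fe_params()] object.
#' @return The final `disorder_assignment`, with the committed trajectory
#'   (a list of ordered vectors, starting at all-ordered) in attribute
#'   `"trajectory"`.
#' @export
greedy_internal <- function(m, params = fe_params()) {
  stopifnot(inherits(m, "interaction_matrix"))
  n <- m$n
  blk <- params$block
  if (n < blk) abort("greedy_internal needs n >= params$block")
  ordered <- rep(TRUE, n)
  cur <- free_energy(m, ordered, params)
  trajectory <- list(ordered)
  M <- m$e_attr + m$e_rep
  repeat {
    best <- NULL
    for (s in seq_len(n - blk + 1L)) {
      w <- s:(s + blk - 1L)
      if (!all(ordered[w])) next
      cand <- ordered
      cand[w] <- FALSE
      if (!any(cand)) next
      runs <- disorder_runs(cand)
      if (any(runs$loops < params$min_loop_len)) next
      keep <- which(cand)
      dE <- -(sum(M[w, keep]) + sum(M[w, w]) / 2)
      ent <- entropy_terms(cand, params)
      F_ <- cur$breakdown$E + dE - ent$tail_term - ent$loop_term
      if (F_ < cur$breakdown$F && (is.null(best) || F_ < best$F_)) {
        best <- list(F_ = F_, ordered = cand)
      }
    }
    if (is.null(best)) break
    ordered <- best$ordered
    cur <- free_energy(m, ordered, params)
    trajectory[[length(trajectory) + 1L]] <- ordered
  }
  attr(cur, "trajectory") <- trajectory
  cur
}

# --- exhaustive search over all topology-valid assignments ----------------

# Enumerate every ordered/disordered vector of length n whose internal
# disordered runs are >= m_len long, with at least one ordered residue.
# Returns a list with the 0/1 ordered matrix (rows = assignments) and the
# parameter-independent entropy ingredients per assignment.
enumerate_valid_assignments <- function(n, m_len) {
  acc <- new.env(parent = emptyenv())
  acc$k <- 0L
  acc$rows <- vector("list", 1024L)
  push <- function(vec, tail_n, loops) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$rows)) {
      acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    }
    acc$rows[[acc$k]] <- list(vec, tail_n, loops)
  }
  # Build run by run. state: position `pos` (next free), whether previous
  # run was ordered, accumulated vector.
  recurse <- function(vec, pos, prev_ordered, tail_n, loops) {
    if (pos > n) {
      push(vec, tail_n, loops)
      return(invisible())
    }
    remaining <- n - pos + 1L
    if (prev_ordered || pos == 1L) {
      # may start a disordered run here (or an ordered one, handled below)
      if (pos == 1L || pos + 0L <= n) {
        # disordered run of length len
        for (len in seq_len(remaining)) {
          end <- pos + len - 1L
          touches_term <- pos == 1L || end == n
          if (!touches_term && len < m_len) next
          if (end == n && pos == 1L) next # all-disordered excluded
          v <- vec
          v[pos:end] <- FALSE
          recurse(v, end + 1L,
                  prev_ordered = FALSE,
                  tail_n = tail_n + if (touches_term) len else 0L,
                  loops = if (touches_term) loops else c(loops, len))
        }
      }
    }
    if (pos == 1L || !prev_ordered) {
      # ordered run of length len
      for (len in seq_len(remaining)) {
        end <- pos + len - 1L
        v <- vec
        v[pos:end] <- TRUE
        recurse(v, end + 1L, prev_ordered = TRUE, tail_n, loops)
      }
    }
  }
  recurse(rep(NA, n), 1L, prev_ordered = TRUE, 0L, integer())
  rows <- acc$rows[seq_len(acc$k)]
  O <- do.call(rbind, lapply(rows, `[[`, 1L))
  tail_n <- vapply(rows, `[[`, integer(1), 2L)
  loops <- lapply(rows, `[[`, 3L)
  list(
    O = O,
    tail_n = tail_n,
    n_loops = vapply(loops, length, integer(1)),
    sum_log_loops = vapply(loops, function(l) sum(log(l)), numeric(1)),
    n_disordered = rowSums(!O)
  )
}

assignment_space_cache <- new.env(parent = emptyenv())

valid_assignments <- function(n, m_len) {
  key <- paste0(n, "_", m_len)
  if (is.null(assignment_space_cache[[key]])) {
    assignment_space_cache[[key]] <- enumerate_valid_assignments(n, m_len)
  }
  assignment_space_cache[[key]]
}

#' Exhaustive global search (test oracle)
#'
#' Enumerates every ordered/disordered assignment satisfying the topology
#' rules (internal runs at least `min_loop_len` long, at least one ordered
#' residue) and returns the global minimum-F assignment under the same tie
#' rules as the other searches. Exponential in `n`; refused above `max_n`.
#'
#' @param m An `interaction_matrix`.
#' @param params An [fe_params()] object.
#' @param max_n Largest `n` accepted (default 24).
#' @return The optimal `disorder_assignment`.
#' @export
exhaustive_search <- function(m, params = fe_params(), max_n = 24L) {
  stopifnot(inherits(m, "interaction_matrix"))
  n <- m$n
  if (n > max_n) {
    abort(sprintf("exhaustive_search refused: n = %d exceeds max_n = %d",
                  n, max_n))
  }
  space <- valid_assignments(n, params$min_loop_len)
  M <- m$e_attr + m$e_rep
  O <- space$O
  E <- rowSums((O %*% M) * O) / 2
  entropy <- params$E_d * space$tail_n +
    params$beta * (space$sum_log_loops - space$n_loops * log(params$L0))
  F_ <- E - entropy
  cand <- which(F_ == min(F_))
  if (length(cand) > 1L) {
    cand <- cand[space$n_disordered[cand] == min(space$n_disordered[cand])]
  }
  best <- cand[1L]
  for (k in cand[-1L]) {
    if (better_assignment(F_[k], as.logical(O[k, ]),
                          F_[best], as.logical(O[best, ]))) {
      best <- k
    }
  }
  free_energy(m, as.logical(O[best, ]), params)
}
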