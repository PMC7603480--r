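#' @include AllClasses.R
NULL

# Boltzmann constant in eV/K (CODATA).
.KB_EV <- 8.617333262e-5

#' Default isolated-atom total energies (eV)
#'
#' Reference energies of the isolated neutral atoms used to convert
#' between total and atomization energies. The defaults are rough
#' all-electron magnitudes for H, C and O; they are configuration, not a
#' physics claim -- only differences enter any prediction.
#'
#' @return named numeric vector, element symbol -> energy (eV).
#' @export
defaultAtomicReferences <- function() {
  c(H = -13.6, C = -1029.0, O = -2041.3)
}

# Element count table of a character vector of symbols.
.elementCounts <- function(elements) {
  tab <- table(elements)
  stats::setNames(as.integer(tab), names(tab))
}

# Weighted element counts of one side of a reaction.
.sideElementCounts <- function(side, molSet) {
  counts <- integer()
  for (i in seq_along(side)) {
    m <- molSet@molecules[[names(side)[i]]]
    tab <- .elementCounts(m@elements) * side[[i]]
    for (el in names(tab))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + tab[[el]]
  }
  counts[order(names(counts))]
}

# Returns character() if balanced, else messages naming the imbalance.
.reactionElementImbalance <- function(reaction, molSet) {
  e <- .sideElementCounts(reaction@educts, molSet)
  p <- .sideElementCounts(reaction@products, molSet)
  els <- sort(union(names(e), names(p)))
  bad <- character()
  for (el in els) {
    ne <- if (el %in% names(e)) e[[el]] else 0L
    np <- if (el %in% names(p)) p[[el]] else 0L
    if (ne != np) bad <- c(bad, sprintf("%s: %d vs %d", el, ne, np))
  }
  bad
}

# Total bond order used at each atom of a MolGraph.
.graphUsedValence <- function(graph) {
  used <- integer(length(graph@elements))
  b <- graph@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      used[b[k, 1]] <- used[b[k, 1]] + b[k, 3]
      used[b[k, 2]] <- used[b[k, 2]] + b[k, 3]
    }
  }
  used
}

.graphIsConnected <- function(graph) {
  n <- length(graph@elements)
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  b <- graph@bonds
  if (!nrow(b)) return(FALSE)
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

# Deterministic integer sub-seed derived from a master seed, kept < 2^31.
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
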