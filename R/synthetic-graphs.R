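#' @include AllClasses.R utils.R
NULL

#' Construct a MolGraph
#'
#' @param elements character vector of C/H/O symbols.
#' @param bonds integer matrix with columns i, j, order (i < j), or
#'   \code{NULL} for a single free atom.
#' @param freeVal integer vector of free (radical) valences per atom;
#'   default: every valence not used by bonds is saturated, i.e. zero
#'   free valences is NOT assumed -- pass explicitly for radicals.
#' @return a validated \linkS4class{MolGraph}.
#' @export
MolGraph <- function(elements, bonds = NULL, freeVal = NULL) {
  if (is.null(bonds))
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (is.null(freeVal)) freeVal <- integer(length(elements))
  g <- new("MolGraph", elements = as.character(elements), bonds = bonds,
           freeVal = as.integer(freeVal))
  g
}

# ---- canonical form ------------------------------------------------------
# Iterative neighborhood (Weisfeiler-Lehman) refinement over the heavy
# skeleton, followed by minimization of the serialized form over all
# orderings compatible with the refined color classes. Exact for the
# small graphs handled here (<= 6 heavy atoms).

.permutationsOf <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n))
    for (rest in .permutationsOf(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# elements/bonds describe the heavy skeleton; nH/fv are per-atom labels.
.canonicalHeavy <- function(elements, bonds, nH, fv) {
  n <- length(elements)
  label <- sprintf("%s|%d|%d", elements, nH, fv)
  if (n == 1L) return(label)
  adj <- vector("list", n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  colors <- match(label, sort(unique(label)))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nbs <- if (is.null(nb)) "" else
        paste(sort(sprintf("%d:%d", nb[, 2], colors[nb[, 1]])), collapse = ",")
      sprintf("%d(%s)", colors[i], nbs)
    }, character(1))
    newColors <- match(sig, sort(unique(sig)))
    if (identical(newColors, colors)) break
    colors <- newColors
  }
  classes <- split(seq_len(n), colors)        # ordered by canonical color rank
  classPerms <- lapply(classes, .permutationsOf)
  serialize <- function(ord) {
    pos <- integer(n); pos[ord] <- seq_len(n)
    bstr <- if (nrow(bonds)) {
      bi <- pmin(pos[bonds[, 1]], pos[bonds[, 2]])
      bj <- pmax(pos[bonds[, 1]], pos[bonds[, 2]])
      paste(sort(sprintf("%02d-%02d:%d", bi, bj, bonds[, 3])), collapse = ";")
    } else ""
    paste(paste(label[ord], collapse = ","), bstr, sep = "#")
  }
  best <- NULL
  rec <- function(idx, acc) {
    if (idx > length(classPerms)) {
      s <- serialize(unlist(acc, use.names = FALSE))
      if (is.null(best) || s < best) best <<- s
      return()
    }
    for (p in classPerms[[idx]]) rec(idx + 1L, c(acc, list(p)))
  }
  rec(1L, list())
  best
}

#' Canonical string of a molecular graph
#'
#' Isomorphism-invariant label: hydrogens are folded into per-heavy-atom
#' counts and the heavy skeleton is canonicalized by iterative
#' neighborhood refinement with exhaustive tie-breaking. Two MolGraphs
#' are the same molecule iff their canonical strings match.
#'
#' @param graph a \linkS4class{MolGraph}.
#' @return character canonical form.
#' @export
canonicalForm <- function(graph) {
  el <- graph@elements
  heavy <- which(el != "H")
  if (!length(heavy))
    return(sprintf("Honly|%d|%d", length(el), sum(graph@freeVal)))
  b <- graph@bonds
  nH <- integer(length(heavy))
  names(nH) <- heavy
  hb <- logical(nrow(b))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (el[i] == "H" || el[j] == "H") {
      hb[k] <- TRUE
      hv <- if (el[i] == "H") j else i
      nH[as.character(hv)] <- nH[as.character(hv)] + 1L
    }
  }
  hbonds <- b[!hb, , drop = FALSE]
  remap <- match(seq_along(el), heavy)
  if (nrow(hbonds)) {
    hbonds[, 1] <- remap[hbonds[, 1]]
    hbonds[, 2] <- remap[hbonds[, 2]]
  }
  .canonicalHeavy(el[heavy], hbonds, unname(nH), graph@freeVal[heavy])
}

# ---- enumeration ---------------------------------------------------------

# Connected heavy-atom multigraph skeletons (no hydrogens) up to
# maxHeavy atoms, grown one atom at a time with canonical deduplication.
.enumerateSkeletons <- function(maxHeavy, allowRings = TRUE) {
  mkKey <- function(el, bonds) .canonicalHeavy(el, bonds,
                                               integer(length(el)),
                                               integer(length(el)))
  current <- list(list(elements = "C",
                       bonds = matrix(integer(0), ncol = 3)),
                  list(elements = "O",
                       bonds = matrix(integer(0), ncol = 3)))
  all <- current
  if (maxHeavy >= 2L) for (k in 2:maxHeavy) {
    seen <- new.env(hash = TRUE)
    nxt <- list()
    for (sk in current) {
      n <- length(sk$elements)
      used <- integer(n)
      if (nrow(sk$bonds)) for (r in seq_len(nrow(sk$bonds))) {
        used[sk$bonds[r, 1]] <- used[sk$bonds[r, 1]] + sk$bonds[r, 3]
        used[sk$bonds[r, 2]] <- used[sk$bonds[r, 2]] + sk$bonds[r, 3]
      }
      slack <- .MAX_VALENCE[sk$elements] - used
      combos <- as.matrix(expand.grid(rep(list(0:2), n)))
      for (newEl in c("C", "O")) {
        maxNew <- .MAX_VALENCE[[newEl]]
        for (ci in seq_len(nrow(combos))) {
          o <- combos[ci, ]
          tot <- sum(o)
          if (tot < 1L || tot > maxNew) next
          if (any(o > slack)) next
          nBonded <- sum(o > 0)
          if (!allowRings && nBonded > 1L) next
          el2 <- c(sk$elements, newEl)
          add <- cbind(which(o > 0), n + 1L, o[o > 0])
          bonds2 <- rbind(sk$bonds, add)
          key <- mkKey(el2, bonds2)
          if (!exists(key, envir = seen)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- list(elements = el2, bonds = bonds2)
          }
        }
      }
    }
    all <- c(all, nxt)
    current <- nxt
  }
  all
}

#' Enumerate CHO molecules up to a heavy-atom limit
#'
#' Exhaustive, duplicate-free enumeration of connected C/H/O multigraphs
#' (bond orders 1 and 2) under the valence rules C:4, O:2, H:1.
#' Hydrogens either saturate every free valence (closed-shell species)
#' or are partially omitted, leaving free valences that mark radical
#' sites -- combinatorially, the radicals dominate the census, as in
#' real radical-rich reference databases. The hydrogen-only species H2
#' (and the H atom when radicals are allowed) are included.
#'
#' @param maxHeavy maximum number of non-hydrogen atoms (>= 1).
#' @param allowRadicals include open-shell species.
#' @param allowRings allow cyclic skeletons (rings can only occur for 3+
#'   heavy atoms).
#' @return named list of \linkS4class{MolGraph}; names are canonical
#'   forms, order is deterministic (heavy count, atom count, canonical
#'   form).
#' @export
enumerateMolecules <- function(maxHeavy, allowRadicals = TRUE,
                               allowRings = TRUE) {
  if (maxHeavy < 1L) stop("maxHeavy must be >= 1")
  skeletons <- .enumerateSkeletons(maxHeavy, allowRings)
  seen <- new.env(hash = TRUE)
  out <- list()
  keys <- character()
  addMol <- function(g) {
    key <- canonicalForm(g)
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <<- g
      keys[length(keys) + 1L] <<- key
    }
  }
  for (sk in skeletons) {
    n <- length(sk$elements)
    used <- integer(n)
    if (nrow(sk$bonds)) for (r in seq_len(nrow(sk$bonds))) {
      used[sk$bonds[r, 1]] <- used[sk$bonds[r, 1]] + sk$bonds[r, 3]
      used[sk$bonds[r, 2]] <- used[sk$bonds[r, 2]] + sk$bonds[r, 3]
    }
    free <- .MAX_VALENCE[sk$elements] - used
    hChoices <- if (allowRadicals)
      lapply(free, function(f) 0:f) else lapply(free, identity)
    grid <- as.matrix(expand.grid(hChoices))
    for (gi in seq_len(nrow(grid))) {
      h <- as.integer(grid[gi, ])
      nh <- sum(h)
      el <- c(sk$elements, rep("H", nh))
      hb <- NULL
      if (nh) {
        parent <- rep(seq_len(n), h)
        hb <- cbind(parent, n + seq_len(nh), 1L)
      }
      bonds <- rbind(sk$bonds, hb)
      fv <- c(free - h, integer(nh))
      addMol(MolGraph(el, bonds, fv))
    }
  }
  addMol(MolGraph(c("H", "H"), cbind(1L, 2L, 1L), c(0L, 0L)))
  if (allowRadicals) addMol(MolGraph("H", NULL, 1L))
  ord <- order(vapply(out, nHeavy, integer(1)),
               vapply(out, nAtoms, integer(1)), keys)
  stats::setNames(out[ord], keys[ord])
}

#' Molecular formula of a graph
#'
#' @param graph a \linkS4class{MolGraph}.
#' @return Hill-style formula string, e.g. \code{"C2H4O"}.
#' @export
graphFormula <- function(graph) {
  tab <- .elementCounts(graph@elements)
  part <- function(e) {
    if (!e %in% names(tab)) return("")
    if (tab[[e]] == 1L) e else paste0(e, tab[[e]])
  }
  paste0(part("C"), part("H"), part("O"))
}

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph %s: %d atoms, %d bonds, %d free valence(s)\n",
              graphFormula(object), nAtoms(object), nrow(object@bonds),
              sum(object@freeVal)))
})

#' Enumerate homolytic single-bond cleavage reactions
#'
#' For every molecule and every order-1 bond, cleave homolytically (one
#' new free valence on each side). A reaction A -> B + C is kept only if
#' it splits the molecule in two and both fragments' canonical forms are
#' present in the molecule set; with \code{breakDoubleBonds} the first
#' bond of a double bond may also break, giving single-product diradical
#' ring/pi-opening reactions A -> D.
#'
#' @param graphs named list of \linkS4class{MolGraph} with molecule ids
#'   as names (as produced by \code{\link{makeFixture}}'s id
#'   assignment; canonical forms may also be used as ids).
#' @param breakDoubleBonds also reduce double bonds to order 1
#'   (default off).
#' @return data.frame with columns educt, product1, product2 (NA for
#'   single-product reactions) listing each distinct reaction once.
#' @export
enumerateBondBreaking <- function(graphs, breakDoubleBonds = FALSE) {
  canon2id <- stats::setNames(names(graphs),
                              vapply(graphs, canonicalForm, character(1)))
  rows <- list()
  seenRxn <- new.env(hash = TRUE)
  for (aid in names(graphs)) {
    g <- graphs[[aid]]
    b <- g@bonds
    if (!nrow(b)) next
    for (k in seq_len(nrow(b))) {
      ord <- b[k, 3]
      if (ord == 1L) {
        frag <- .cleaveBond(g, k)
      } else if (breakDoubleBonds) {
        frag <- list(.reduceBond(g, k))
      } else next
      if (length(frag) == 2L) {
        c1 <- canonicalForm(frag[[1]]); c2 <- canonicalForm(frag[[2]])
        if (!c1 %in% names(canon2id) || !c2 %in% names(canon2id)) next
        p <- sort(c(canon2id[[c1]], canon2id[[c2]]))
        key <- paste(aid, p[1], p[2], sep = ">")
        if (!exists(key, envir = seenRxn)) {
          assign(key, TRUE, envir = seenRxn)
          rows[[length(rows) + 1L]] <- data.frame(
            educt = aid, product1 = p[1], product2 = p[2],
            stringsAsFactors = FALSE)
        }
      } else {
        c1 <- canonicalForm(frag[[1]])
        if (!c1 %in% names(canon2id)) next
        p1 <- canon2id[[c1]]
        if (identical(p1, aid)) next
        key <- paste(aid, p1, sep = ">")
        if (!exists(key, envir = seenRxn)) {
          assign(key, TRUE, envir = seenRxn)
          rows[[length(rows) + 1L]] <- data.frame(
            educt = aid, product1 = p1, product2 = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(educt = character(), product1 = character(),
                      product2 = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Remove bond k entirely; returns list of 1 (still connected) or 2
# fragment MolGraphs with a new free valence at each broken end.
.cleaveBond <- function(g, k) {
  b <- g@bonds
  i <- b[k, 1]; j <- b[k, 2]
  fv <- g@freeVal
  fv[i] <- fv[i] + 1L; fv[j] <- fv[j] + 1L
  bonds2 <- b[-k, , drop = FALSE]
  comp <- .componentsOf(length(g@elements), bonds2)
  build <- function(idx) {
    remap <- match(seq_along(g@elements), idx)
    bb <- bonds2[bonds2[, 1] %in% idx & bonds2[, 2] %in% idx, ,
                 drop = FALSE]
    if (nrow(bb)) { bb[, 1] <- remap[bb[, 1]]; bb[, 2] <- remap[bb[, 2]] }
    MolGraph(g@elements[idx], bb, fv[idx])
  }
  lapply(split(seq_along(comp), comp), build)
}

# Reduce bond k's order by one (double -> single), adding one free
# valence at each end; connectivity unchanged.
.reduceBond <- function(g, k) {
  b <- g@bonds
  b[k, 3] <- b[k, 3] - 1L
  fv <- g@freeVal
  fv[b[k, 1]] <- fv[b[k, 1]] + 1L
  fv[b[k, 2]] <- fv[b[k, 2]] + 1L
  MolGraph(g@elements, b, fv)
}

.componentsOf <- function(n, bonds) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    a <- find(bonds[k, 1]); b <- find(bonds[k, 2])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}
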