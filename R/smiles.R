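#' Parse a SMILES string into a molecular graph
#'
#' A small SMILES reader covering the organic subset (B, C, N, O, P, S, F,
#' Cl, Br, I), bracket atoms with explicit hydrogen counts and charges,
#' branches, ring-closure digits and single/double/triple bonds. Implicit
#' hydrogens are assigned from the standard SMILES valence model
#' (C 4; N 3,5; O 2; P 3,5; S 2,4,6; halogens 1; B 3). Aromatic (lowercase)
#' atoms are not supported: supply kekulized SMILES, as all writers in this
#' package do.
#'
#' @param smiles A single SMILES string.
#' @return A list with two tibbles: `atoms` (columns `idx`, `element`,
#'   `charge`, `n_h` — implicit plus bracket hydrogens) and `bonds`
#'   (columns `from`, `to`, `order`, `in_ring`).
#' @examples
#' g <- parse_smiles("CP(C)C") # trimethylphosphine
#' sum(g$atoms$n_h)            # 9 hydrogens
#' @export
parse_smiles <- function(smiles) {
  if (!is_string(smiles)) abort("`smiles` must be a single string.")
  toks <- tokenize_smiles(smiles)

  elements <- character()
  charges <- integer()
  expl_h <- integer() # NA => organic subset, fill by valence model
  bonds <- list()
  prev <- NA_integer_ # atom the next bond attaches to
  stack <- integer()
  ring_open <- list() # digit -> c(atom, order)
  pending_order <- NA_real_

  add_bond <- function(a, b, order) {
    bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  }

  for (tok in toks) {
    if (tok$kind == "atom") {
      elements <- c(elements, tok$element)
      charges <- c(charges, tok$charge)
      expl_h <- c(expl_h, tok$n_h)
      idx <- length(elements)
      if (!is.na(prev)) {
        add_bond(prev, idx, if (is.na(pending_order)) 1 else pending_order)
      }
      pending_order <- NA_real_
      prev <- idx
    } else if (tok$kind == "bond") {
      pending_order <- tok$order
    } else if (tok$kind == "open") {
      stack <- c(stack, prev)
    } else if (tok$kind == "close") {
      if (length(stack) == 0L) abort("Unbalanced ')' in SMILES.")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok$kind == "ring") {
      key <- as.character(tok$label)
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- c(prev, if (is.na(pending_order)) 1 else pending_order)
        pending_order <- NA_real_
      } else {
        opened <- ring_open[[key]]
        ring_open[[key]] <- NULL
        order <- if (!is.na(pending_order)) pending_order else opened[2]
        add_bond(opened[1], prev, order)
        pending_order <- NA_real_
      }
    }
  }
  if (length(stack) > 0L) abort("Unbalanced '(' in SMILES.")
  if (length(ring_open) > 0L) abort("Unclosed ring bond in SMILES.")
  if (length(elements) == 0L) abort("SMILES contains no atoms.")

  bond_tbl <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    tibble(from = as.integer(m[, 1]), to = as.integer(m[, 2]), order = m[, 3])
  } else {
    tibble(from = integer(), to = integer(), order = double())
  }

  n_h <- assign_implicit_h(elements, charges, expl_h, bond_tbl)
  bond_tbl$in_ring <- flag_ring_bonds(length(elements), bond_tbl)

  list(
    atoms = tibble(
      idx = seq_along(elements), element = elements,
      charge = charges, n_h = n_h
    ),
    bonds = bond_tbl
  )
}

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  push <- function(t) toks[[length(toks) + 1L]] <<- t
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) abort("Unterminated bracket atom in SMILES.")
      push(parse_bracket_atom(paste(chars[(i + 1L):(j - 1L)], collapse = "")))
      i <- j + 1L
    } else if (ch %in% c("B", "C") && i < n && chars[i + 1L] %in% c("r", "l")) {
      two <- paste0(ch, chars[i + 1L])
      if (!two %in% c("Br", "Cl")) abort(sprintf("Unknown element '%s' in SMILES.", two))
      push(list(kind = "atom", element = two, charge = 0L, n_h = NA_integer_))
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      push(list(kind = "atom", element = ch, charge = 0L, n_h = NA_integer_))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      abort(paste0(
        "Aromatic (lowercase) SMILES atoms are not supported; ",
        "supply a kekulized SMILES string."
      ))
    } else if (ch == "-") {
      push(list(kind = "bond", order = 1))
      i <- i + 1L
    } else if (ch == "=") {
      push(list(kind = "bond", order = 2))
      i <- i + 1L
    } else if (ch == "#") {
      push(list(kind = "bond", order = 3))
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) { # cis/trans markers: treat as single
      push(list(kind = "bond", order = 1))
      i <- i + 1L
    } else if (ch == "(") {
      push(list(kind = "open"))
      i <- i + 1L
    } else if (ch == ")") {
      push(list(kind = "close"))
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push(list(kind = "ring", label = as.integer(ch)))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) abort("Truncated '%' ring label in SMILES.")
      push(list(kind = "ring", label = as.integer(paste0(chars[i + 1L], chars[i + 2L]))))
      i <- i + 3L
    } else if (ch == ".") {
      abort("Disconnected (dot-separated) SMILES are not supported.")
    } else {
      abort(sprintf("Unexpected character '%s' in SMILES.", ch))
    }
  }
  toks
}

parse_bracket_atom <- function(body) {
  m <- regmatches(
    body,
    regexec("^([0-9]*)([A-Z][a-z]?)(@{0,2})(H([0-9]*))?([+-]+[0-9]*)?(:[0-9]+)?$", body)
  )[[1]]
  if (length(m) == 0L) abort(sprintf("Cannot parse bracket atom '[%s]'.", body))
  element <- m[3]
  n_h <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
  charge <- 0L
  if (m[7] != "") {
    signs <- gsub("[0-9]", "", m[7])
    num <- gsub("[+-]", "", m[7])
    unit <- if (substr(signs, 1, 1) == "+") 1L else -1L
    charge <- if (num != "") unit * as.integer(num) else unit * nchar(signs)
  }
  list(kind = "atom", element = element, charge = charge, n_h = n_h)
}

assign_implicit_h <- function(elements, charges, expl_h, bonds) {
  bond_sum <- numeric(length(elements))
  for (k in seq_len(nrow(bonds))) {
    bond_sum[bonds$from[k]] <- bond_sum[bonds$from[k]] + bonds$order[k]
    bond_sum[bonds$to[k]] <- bond_sum[bonds$to[k]] + bonds$order[k]
  }
  n_h <- expl_h
  for (i in seq_along(elements)) {
    if (!is.na(n_h[i])) next # bracket atom: hydrogen count is explicit
    val <- DEFAULT_VALENCES[[elements[i]]]
    if (is.null(val)) abort(sprintf("No valence model for element '%s'.", elements[i]))
    fit <- val[val >= bond_sum[i]]
    n_h[i] <- if (length(fit)) as.integer(fit[1] - bond_sum[i]) else 0L
  }
  n_h
}

# A bond is in a ring iff its endpoints stay connected after removing it.
flag_ring_bonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$from[k]]] <- c(adj[[bonds$from[k]]], k)
    adj[[bonds$to[k]]] <- c(adj[[bonds$to[k]]], k)
  }
  vapply(seq_len(nrow(bonds)), function(k) {
    src <- bonds$from[k]
    dst <- bonds$to[k]
    seen <- logical(n_atoms)
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      a <- queue[1]
      queue <- queue[-1]
      for (kk in adj[[a]]) {
        if (kk == k) next
        b <- if (bonds$from[kk] == a) bonds$to[kk] else bonds$from[kk]
        if (!seen[b]) {
          if (b == dst) return(TRUE)
          seen[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Count atoms (including hydrogens) in a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return Integer atom count, hydrogens included.
#' @examples
#' smiles_atom_count("CP(C)C") # 13
#' @export
smiles_atom_count <- function(smiles) {
  g <- parse_smiles(smiles)
  as.integer(nrow(g$atoms) + sum(g$atoms$n_h))
}

#' Count rotatable bonds in a SMILES string (strict definition)
#'
#' Counts single, acyclic bonds between two non-terminal heavy atoms, with
#' the strict exclusions used by common cheminformatics toolkits: atoms in
#' triple bonds, amide/ester/thioester carbonyl--heteroatom bonds
#' (C(=O,N,S)–[N,O,S]) and symmetric terminal rotors (CF3, CCl3, CBr3,
#' C(CH3)3) do not rotate.
#'
#' @param smiles A single SMILES string.
#' @return Integer rotatable-bond count.
#' @examples
#' smiles_rotatable_bonds("CP(C)C")          # 0: all methyls terminal
#' smiles_rotatable_bonds("CCP(=O)(OCC)OCC") # 5
#' @export
smiles_rotatable_bonds <- function(smiles) {
  g <- parse_smiles(smiles)
  atoms <- g$atoms
  bonds <- g$bonds
  if (nrow(bonds) == 0L) return(0L)

  degree <- integer(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    degree[bonds$from[k]] <- degree[bonds$from[k]] + 1L
    degree[bonds$to[k]] <- degree[bonds$to[k]] + 1L
  }
  in_triple <- logical(nrow(atoms))
  dbl_het <- logical(nrow(atoms)) # carbon double-bonded to N/O/S
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 3) in_triple[c(bonds$from[k], bonds$to[k])] <- TRUE
    if (bonds$order[k] == 2) {
      f <- bonds$from[k]
      t <- bonds$to[k]
      if (atoms$element[f] == "C" && atoms$element[t] %in% c("N", "O", "S")) dbl_het[f] <- TRUE
      if (atoms$element[t] == "C" && atoms$element[f] %in% c("N", "O", "S")) dbl_het[t] <- TRUE
    }
  }

  neighbours <- function(i) {
    c(bonds$to[bonds$from == i], bonds$from[bonds$to == i])
  }
  symmetric_rotor <- function(i, partner) {
    if (atoms$element[i] != "C") return(FALSE)
    nb <- setdiff(neighbours(i), partner)
    if (length(nb) != 3L) return(FALSE)
    el <- atoms$element[nb]
    if (all(el == el[1]) && el[1] %in% c("F", "Cl", "Br")) return(TRUE)
    all(el == "C" & degree[nb] == 1L & atoms$n_h[nb] == 3L)
  }

  n_rot <- 0L
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] != 1 || bonds$in_ring[k]) next
    f <- bonds$from[k]
    t <- bonds$to[k]
    if (degree[f] < 2L || degree[t] < 2L) next
    if (in_triple[f] || in_triple[t]) next
    if (symmetric_rotor(f, t) || symmetric_rotor(t, f)) next
    amide_like <-
      (dbl_het[f] && atoms$element[t] %in% c("N", "O", "S")) ||
      (dbl_het[t] && atoms$element[f] %in% c("N", "O", "S"))
    if (amide_like) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

smiles_phosphorus_count <- function(smiles) {
  sum(parse_smiles(smiles)$atoms$element == "P")
}
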