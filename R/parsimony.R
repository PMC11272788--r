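# Parsimony character-fit statistics -------------------------------------
#
# Post-hoc scoring of a morphological character matrix on a fixed tree:
# per-character minimum steps by dynamic programming (Fitch for unordered
# characters, Farris/Wagner for ordered ones, both via the Sankoff
# recursion with the appropriate step matrix), the classical character-fit
# indices CI = sum(m)/sum(s) and RI = (sum(g)-sum(s))/(sum(g)-sum(m)), and
# one accelerated-transformation reconstruction of state changes per
# branch. Heuristic tree search is out of scope: the tree is an input.

#' Read a morphological character matrix (TNT or NEXUS)
#'
#' Supports TNT `xread` blocks and NEXUS `DATA`/`CHARACTERS` blocks
#' (non-interleaved or interleaved). Missing data `?`, inapplicable `-`
#' and polymorphic cells (`[01]` in TNT, `{01}` or `(01)` in NEXUS) are
#' preserved. Character ordering is read from a TNT `ccode` command
#' (`+` ordered, `-` unordered, 0-based indices and `a.b` ranges) when
#' present; all characters default to unordered ("equally weighted
#' parsimony").
#'
#' @param path File to read.
#' @param format `"tnt"`, `"nexus"`, or `"auto"` (detected from content).
#' @return A `character_matrix` object: list with `taxa`, `states` (a
#'   taxa x characters matrix of state strings, e.g. `"0"`, `"02"`, `"?"`),
#'   `symbols` (state alphabet actually observed), `n_char` and `ordered`
#'   (logical per character).
#' @export
read_character_matrix <- function(path, format = c("auto", "tnt", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE))) "nexus" else "tnt"
  }
  switch(format,
    tnt = read_matrix_tnt(lines),
    nexus = read_matrix_nexus(lines)
  )
}

new_character_matrix <- function(taxa, states, ordered = NULL) {
  states <- matrix(as.character(states), nrow = length(taxa))
  rownames(states) <- taxa
  symbols <- sort(unique(unlist(strsplit(states[!(states %in% c("?", "-"))], ""))))
  if (is.null(ordered)) ordered <- rep(FALSE, ncol(states))
  structure(
    list(
      taxa = taxa, states = states, symbols = symbols,
      n_char = ncol(states), ordered = ordered
    ),
    class = "character_matrix"
  )
}

# split a row string like "01[02]?-" into per-character state strings
split_state_row <- function(row, line_no, open = "[", close = "]") {
  chars <- strsplit(row, "")[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("[", "{", "(")) {
      cl <- c("[" = "]", "{" = "}", "(" = ")")[ch]
      j <- i + 1
      grp <- character(0)
      while (j <= length(chars) && chars[j] != cl) {
        grp <- c(grp, chars[j])
        j <- j + 1
      }
      if (j > length(chars)) {
        abort(paste0("unclosed polymorphism bracket at line ", line_no))
      }
      out <- c(out, paste(sort(grp), collapse = ""))
      i <- j + 1
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  out
}

read_matrix_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  x_at <- regexpr("xread", txt, ignore.case = TRUE)
  if (x_at < 0) abort("no xread block found")
  body <- substr(txt, x_at + 5, nchar(txt))
  semi <- regexpr(";", body)
  if (semi < 0) abort("xread block not terminated by ';'")
  block <- substr(body, 1, semi - 1)
  # drop a quoted title if present
  block <- sub("^\\s*'[^']*'", "", block)
  toks <- strsplit(trimws(block), "\\s+")[[1]]
  if (length(toks) < 2) abort("xread block missing dimensions")
  n_char <- suppressWarnings(as.integer(toks[1]))
  n_tax <- suppressWarnings(as.integer(toks[2]))
  if (is.na(n_char) || is.na(n_tax)) abort("malformed xread dimensions")
  rest <- toks[-(1:2)]
  if (length(rest) %% 2 != 0) abort("xread matrix rows must be 'taxon states' pairs")
  taxa_raw <- rest[seq(1, length(rest), by = 2)]
  rows_raw <- rest[seq(2, length(rest), by = 2)]
  # interleaved blocks repeat taxa: accumulate
  acc <- list()
  for (i in seq_along(taxa_raw)) {
    acc[[taxa_raw[i]]] <- paste0(acc[[taxa_raw[i]]] %||% "", rows_raw[i])
  }
  taxa <- names(acc)
  if (length(taxa) != n_tax) {
    abort(sprintf("xread declares %d taxa but %d found", n_tax, length(taxa)))
  }
  states <- t(vapply(taxa, function(tx) {
    st <- split_state_row(acc[[tx]], NA)
    if (length(st) != n_char) {
      abort(sprintf(
        "taxon %s has %d characters, expected %d", tx, length(st), n_char
      ))
    }
    st
  }, character(n_char)))
  ordered <- rep(FALSE, n_char)
  cc_at <- regmatches(txt, gregexpr("cc(ode)?\\s*[^;]*;", txt, ignore.case = TRUE))[[1]]
  for (cc in cc_at) {
    ordered <- apply_ccode(cc, ordered)
  }
  new_character_matrix(taxa, states, ordered)
}

# TNT ccode: '+' marks following (0-based) characters ordered, '-' unordered;
# 'a.b' is an inclusive range
apply_ccode <- function(cc, ordered) {
  body <- sub(";\\s*$", "", sub("^cc(ode)?\\s*", "", cc, ignore.case = TRUE))
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  mode <- NA
  for (tk in toks) {
    if (tk %in% c("+", "-")) {
      mode <- tk
    } else if (grepl("^[0-9]+(\\.[0-9]+)?$", tk) && !is.na(mode)) {
      if (grepl("\\.", tk)) {
        ab <- as.integer(strsplit(tk, "\\.")[[1]])
        idx <- (ab[1]:ab[2]) + 1L
      } else {
        idx <- as.integer(tk) + 1L
      }
      idx <- idx[idx >= 1 & idx <= length(ordered)]
      ordered[idx] <- (mode == "+")
    }
  }
  ordered
}

read_matrix_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # strip NEXUS comments
  txt <- gsub("\\[[^]]*\\]", "", txt)
  dims <- regmatches(txt, regexpr("DIMENSIONS[^;]*;", txt, ignore.case = TRUE))
  if (length(dims) == 0) abort("no DIMENSIONS command found")
  n_tax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  n_char <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  if (is.na(n_tax) || is.na(n_char)) abort("malformed DIMENSIONS command")
  mat_at <- regexpr("MATRIX", txt, ignore.case = TRUE)
  if (mat_at < 0) abort("no MATRIX command found")
  body <- substr(txt, mat_at + 6, nchar(txt))
  semi <- regexpr(";", body)
  block <- substr(body, 1, semi - 1)
  rows <- strsplit(trimws(block), "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  acc <- list()
  order_seen <- character(0)
  for (i in seq_along(rows)) {
    m <- regmatches(rows[i], regexec("^('[^']+'|\\S+)\\s+(.*)$", rows[i]))[[1]]
    if (length(m) < 3) abort(paste0("malformed matrix row: ", rows[i]))
    tx <- gsub("^'|'$", "", m[2])
    st <- gsub("\\s", "", m[3])
    if (!tx %in% order_seen) order_seen <- c(order_seen, tx)
    acc[[tx]] <- paste0(acc[[tx]] %||% "", st)
  }
  taxa <- order_seen
  if (length(taxa) != n_tax) {
    abort(sprintf("NEXUS declares NTAX=%d but %d taxa found", n_tax, length(taxa)))
  }
  states <- t(vapply(taxa, function(tx) {
    st <- split_state_row(acc[[tx]], NA)
    if (length(st) != n_char) {
      abort(sprintf(
        "taxon %s has %d characters, expected %d", tx, length(st), n_char
      ))
    }
    st
  }, character(n_char)))
  new_character_matrix(taxa, states)
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf(
    "Character matrix: %d taxa x %d characters (%d ordered), symbols {%s}\n",
    length(x$taxa), x$n_char, sum(x$ordered), paste(x$symbols, collapse = "")
  ))
  invisible(x)
}

#' @rdname read_character_matrix
#' @param x A `character_matrix` (for `tidy`).
#' @param ... Unused.
#' @method tidy character_matrix
#' @export
tidy.character_matrix <- function(x, ...) {
  tibble(
    taxon = rep(x$taxa, x$n_char),
    character = rep(seq_len(x$n_char), each = length(x$taxa)),
    state = as.vector(x$states)
  )
}

# --- scoring ------------------------------------------------------------

# integer state sets per cell; missing/inapplicable = full alphabet
cell_state_sets <- function(states_col, symbols) {
  lapply(states_col, function(cell) {
    if (cell %in% c("?", "-")) {
      seq_along(symbols)
    } else {
      idx <- match(strsplit(cell, "")[[1]], symbols)
      if (anyNA(idx)) abort(paste0("undeclared state symbol in cell '", cell, "'"))
      idx
    }
  })
}

# step-cost matrix over the symbol alphabet: unit costs for unordered
# characters, absolute numeric state differences for ordered ones
step_matrix <- function(symbols, ordered) {
  if (ordered) {
    vals <- suppressWarnings(as.numeric(symbols))
    if (anyNA(vals)) {
      abort("ordered characters require numeric state symbols")
    }
    abs(outer(vals, vals, "-"))
  } else {
    1 - diag(length(symbols))
  }
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) {
    return(tree)
  }
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) {
      return(ape::read.tree(tree))
    }
    return(ape::read.tree(text = tree))
  }
  abort("tree must be a phylo object, a newick string, or a newick file path")
}

# Sankoff cost vectors for one character; returns list(cost = matrix of
# node x state costs, steps = minimum at the root)
sankoff_cost <- function(phy, tip_sets, W) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  S <- nrow(W)
  cost <- matrix(0, n_node, S)
  for (i in seq_len(n_tip)) {
    cost[i, ] <- Inf
    cost[i, tip_sets[[i]]] <- 0
  }
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]
    child <- edge[e, 2]
    child_min <- vapply(seq_len(S), function(s) min(cost[child, ] + W[s, ]), numeric(1))
    cost[parent, ] <- cost[parent, ] + child_min
  }
  root <- edge[nrow(edge), 1]
  list(cost = cost, steps = min(cost[root, ]), root = root, edge = edge)
}

# minimum conceivable steps of one character on any tree
min_steps_anywhere <- function(tip_sets, W, ordered, n_states, symbols) {
  constrained <- tip_sets[vapply(tip_sets, length, integer(1)) < n_states]
  if (length(constrained) == 0) {
    return(0L)
  }
  if (ordered) {
    vals <- as.numeric(symbols)
    lo <- max(vapply(constrained, function(s) min(vals[s]), numeric(1)))
    hi <- min(vapply(constrained, function(s) max(vals[s]), numeric(1)))
    return(as.integer(max(0, lo - hi)))
  }
  observed <- sort(unique(unlist(constrained)))
  for (size in seq_along(observed)) {
    combos <- utils::combn(observed, size, simplify = FALSE)
    for (cmb in combos) {
      if (all(vapply(constrained, function(s) length(intersect(s, cmb)) > 0, logical(1)))) {
        return(size - 1L)
      }
    }
  }
  length(observed) - 1L
}

# maximum steps: the character's score on the star tree (min over a single
# central state of the summed tip costs)
max_steps_star <- function(tip_sets, W, n_states) {
  costs <- vapply(seq_len(n_states), function(z) {
    sum(vapply(tip_sets, function(s) min(W[z, s]), numeric(1)))
  }, numeric(1))
  min(costs)
}

#' Parsimony score of a character matrix on a fixed tree
#'
#' Computes, per character, the minimum number of steps on the given
#' topology (Fitch counting for unordered characters, Farris/Wagner for
#' ordered ones, via the Sankoff recursion), the minimum conceivable steps
#' `m` on any tree, and the maximum steps `g` on the star tree; sums give
#' the tree length, the consistency index CI = sum(m)/sum(s) and the
#' retention index RI = (sum(g)-sum(s))/(sum(g)-sum(m)). Missing (`?`) and
#' inapplicable (`-`) cells behave as the full state set; polymorphic cells
#' allow any of their states at the tip for free.
#'
#' @param tree An `ape` `phylo` object, a newick string, or a path to a
#'   newick file. Tips must be a subset of the matrix taxa; matrix taxa
#'   absent from the tree are ignored.
#' @param matrix A `character_matrix` from [read_character_matrix()] or
#'   [new_character_matrix_from_df()].
#' @return A `parsimony_score` object: list with `tree_length`, `ci`, `ri`
#'   (NA when undefined) and `per_character` (tibble: `character`, `steps`,
#'   `min_steps`, `max_steps`, `ordered`).
#' @export
fitch_length <- function(tree, matrix) {
  phy <- as_phylo(tree)
  stopifnot(inherits(matrix, "character_matrix"))
  missing_tips <- setdiff(phy$tip.label, matrix$taxa)
  if (length(missing_tips) > 0) {
    abort(paste0("tree tips absent from matrix: ", paste(missing_tips, collapse = ", ")))
  }
  symbols <- matrix$symbols
  S <- length(symbols)
  rows <- match(phy$tip.label, matrix$taxa)
  per <- lapply(seq_len(matrix$n_char), function(j) {
    W <- step_matrix(symbols, matrix$ordered[j])
    sets <- cell_state_sets(matrix$states[rows, j], symbols)
    sk <- sankoff_cost(phy, sets, W)
    tibble(
      character = j,
      steps = as.integer(sk$steps),
      min_steps = as.integer(min_steps_anywhere(sets, W, matrix$ordered[j], S, symbols)),
      max_steps = as.integer(max_steps_star(sets, W, S)),
      ordered = matrix$ordered[j]
    )
  })
  per <- dplyr::bind_rows(per)
  s_sum <- sum(per$steps)
  m_sum <- sum(per$min_steps)
  g_sum <- sum(per$max_steps)
  structure(
    list(
      tree_length = s_sum,
      ci = if (s_sum > 0) m_sum / s_sum else NA_real_,
      ri = if (g_sum > m_sum) (g_sum - s_sum) / (g_sum - m_sum) else NA_real_,
      per_character = per,
      n_taxa = length(phy$tip.label),
      n_char = matrix$n_char
    ),
    class = "parsimony_score"
  )
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf(
    "Parsimony score: %d taxa, %d characters\n  tree length %d, CI %s, RI %s\n",
    x$n_taxa, x$n_char, x$tree_length,
    ifelse(is.na(x$ci), "undefined", sprintf("%.3f", x$ci)),
    ifelse(is.na(x$ri), "undefined", sprintf("%.3f", x$ri))
  ))
  invisible(x)
}

#' @rdname fitch_length
#' @param x A `parsimony_score` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy parsimony_score
#' @export
tidy.parsimony_score <- function(x, ...) x$per_character

#' @rdname fitch_length
#' @method glance parsimony_score
#' @export
glance.parsimony_score <- function(x, ...) {
  tibble(
    tree_length = x$tree_length, ci = x$ci, ri = x$ri,
    n_taxa = x$n_taxa, n_char = x$n_char
  )
}

#' Build a character matrix from a data frame
#'
#' Programmatic companion to [read_character_matrix()]: one row per taxon,
#' one column per character, cells as state strings (`"0"`, `"01"` for
#' polymorphism, `"?"` missing, `"-"` inapplicable).
#'
#' @param df Data frame or matrix of state strings with row names (or a
#'   `taxon` column) naming the taxa.
#' @param ordered Logical vector, one per character (default all
#'   unordered).
#' @return A `character_matrix`.
#' @export
new_character_matrix_from_df <- function(df, ordered = NULL) {
  if (is.data.frame(df) && "taxon" %in% names(df)) {
    taxa <- df$taxon
    df <- df[, setdiff(names(df), "taxon"), drop = FALSE]
  } else {
    taxa <- rownames(df)
  }
  if (is.null(taxa)) abort("taxa must be given as row names or a 'taxon' column")
  new_character_matrix(taxa, as.matrix(df), ordered)
}

#' Map character state changes onto branches
#'
#' One most-parsimonious reconstruction per character under accelerated
#' transformation (changes placed as close to the root as ties allow),
#' obtained by backtracking the Sankoff recursion: the root takes its
#' cheapest state and each child the state minimizing its subtree cost plus
#' the step cost from the parent, ties broken in favour of changing (and
#' then the smallest state). The summed cost of the mapped changes equals
#' the tree length.
#'
#' @inheritParams fitch_length
#' @return Tibble with one row per state change: `character`,
#'   `parent_node`, `child_node`, `child_label` (tip label or `node:<id>`),
#'   `from`, `to` (state symbols) and `cost` (steps along that branch).
#' @export
map_changes <- function(tree, matrix) {
  phy <- as_phylo(tree)
  stopifnot(inherits(matrix, "character_matrix"))
  missing_tips <- setdiff(phy$tip.label, matrix$taxa)
  if (length(missing_tips) > 0) {
    abort(paste0("tree tips absent from matrix: ", paste(missing_tips, collapse = ", ")))
  }
  symbols <- matrix$symbols
  S <- length(symbols)
  rows <- match(phy$tip.label, matrix$taxa)
  n_tip <- length(phy$tip.label)
  out <- list()
  for (j in seq_len(matrix$n_char)) {
    W <- step_matrix(symbols, matrix$ordered[j])
    sets <- cell_state_sets(matrix$states[rows, j], symbols)
    sk <- sankoff_cost(phy, sets, W)
    edge <- sk$edge
    assign_state <- integer(n_tip + phy$Nnode)
    root_costs <- sk$cost[sk$root, ]
    assign_state[sk$root] <- which.min(root_costs)
    # preorder: parents before children
    for (e in rev(seq_len(nrow(edge)))) {
      parent <- edge[e, 1]
      child <- edge[e, 2]
      ps <- assign_state[parent]
      tot <- sk$cost[child, ] + W[ps, ]
      cand <- which(tot == min(tot))
      changing <- cand[cand != ps]
      assign_state[child] <- if (length(changing) > 0) min(changing) else min(cand)
    }
    changed <- edge[assign_state[edge[, 1]] != assign_state[edge[, 2]], , drop = FALSE]
    if (nrow(changed) > 0) {
      out[[length(out) + 1]] <- tibble(
        character = j,
        parent_node = changed[, 1],
        child_node = changed[, 2],
        child_label = ifelse(
          changed[, 2] <= n_tip, phy$tip.label[changed[, 2]],
          paste0("node:", changed[, 2])
        ),
        from = symbols[assign_state[changed[, 1]]],
        to = symbols[assign_state[changed[, 2]]],
        cost = W[cbind(assign_state[changed[, 1]], assign_state[changed[, 2]])]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      character = integer(), parent_node = integer(), child_node = integer(),
      child_label = character(), from = character(), to = character(),
      cost = numeric()
    ))
  }
  dplyr::bind_rows(out)
}
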