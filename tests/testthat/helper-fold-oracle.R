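# Exhaustive-enumeration oracle for the builtin folding engine: enumerates
# every nested secondary structure (minimum hairpin loop 3, Watson-Crick +
# GU pairs) of a short sequence and scores each by loop decomposition with
# the engine's own parameter tables. Independent of the dynamic program.

oracle_pairs <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE,
                  GU = TRUE, UG = TRUE)

oracle_hairpin <- function(l, par) {
  if (l < par$min_hairpin) return(Inf)
  if (l <= 9) return(par$hairpin[[as.character(l)]])
  par$hairpin[["9"]] + par$js_coef * par$rt * log(l / 9)
}

oracle_bulge <- function(l, par) {
  if (l < 1) return(Inf)
  if (l <= 6) return(par$bulge[[as.character(l)]])
  par$bulge[["6"]] + par$js_coef * par$rt * log(l / 6)
}

oracle_internal <- function(l, par) {
  if (l < 2) return(Inf)
  if (l <= 10) return(par$internal[[as.character(l)]])
  par$internal[["10"]] + par$js_coef * par$rt * log(l / 10)
}

enum_structures <- function(bases, par) {
  memo <- new.env(parent = emptyenv())
  can_pair <- function(i, j) {
    isTRUE(oracle_pairs[paste0(bases[i], bases[j])])
  }
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)
    ks <- seq(i + par$min_hairpin + 1, j)
    for (k in ks[ks <= j]) {
      if (!can_pair(i, k)) next
      left <- rec(i + 1, k - 1)
      right <- if (k + 1 <= j) rec(k + 1, j) else list(list())
      for (s1 in left) for (s2 in right) {
        out[[length(out) + 1]] <- c(list(c(i, k)), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, length(bases))
}

score_structure <- function(bases, pairs, par) {
  if (length(pairs) == 0) return(0)
  P <- do.call(rbind, pairs)
  e <- 0
  for (r in seq_len(nrow(P))) {
    i <- P[r, 1]; j <- P[r, 2]
    inside <- P[P[, 1] > i & P[, 2] < j, , drop = FALSE]
    if (nrow(inside)) {
      is_child <- vapply(seq_len(nrow(inside)), function(m) {
        !any(inside[, 1] < inside[m, 1] & inside[, 2] > inside[m, 2])
      }, logical(1))
      ch <- inside[is_child, , drop = FALSE]
    } else {
      ch <- inside
    }
    if (nrow(ch) == 0) {
      e <- e + oracle_hairpin(j - i - 1, par)
    } else if (nrow(ch) == 1) {
      p <- ch[1, 1]; q <- ch[1, 2]
      l1 <- p - i - 1; l2 <- j - q - 1
      if (l1 == 0 && l2 == 0) {
        e <- e + par$stack[paste0(bases[i], bases[j]),
                           paste0(bases[p], bases[q])]
      } else if (l1 + l2 > par$max_loop) {
        e <- e + Inf
      } else if (l1 == 0 || l2 == 0) {
        e <- e + oracle_bulge(l1 + l2, par)
      } else {
        e <- e + oracle_internal(l1 + l2, par)
      }
    } else {
      unpaired <- (j - i - 1) - sum(ch[, 2] - ch[, 1] + 1)
      e <- e + par$ml_close + par$ml_branch * nrow(ch) +
        par$ml_unpaired * unpaired
    }
  }
  e
}

oracle_mfe <- function(seq) {
  par <- fold_params()
  bases <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- enum_structures(bases, par)
  min(0, min(vapply(structs, function(s) score_structure(bases, s, par),
                    numeric(1))))
}
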