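# Homozygote-anchored haplotype inference.  Individuals homozygous at an
# anchor locus (DRB1) carry the same haplotype twice, so every allele their
# downstream assays reveal belongs to that one haplotype.  Anchor alleles
# shared by several haplotypes are split by partitioning the anchored
# individuals' downstream profiles; rare anchor alleles without homozygotes
# are recovered by subtracting a known partner haplotype from heterozygous
# individuals.

# ---- profiles -------------------------------------------------------------

# the called allele-set of one assay call: character vector for a clean call,
# character(0) for no product, NA for anything unusable
called_set <- function(call) {
  if (call$status == "no_product") return(character())
  if (call$status == "called") return(sort(call$explanations[[1]]))
  NA_character_
}

# per-individual profile over a set of assays; NULL when any assay unusable
individual_profile <- function(table, id, assay_names) {
  p <- lapply(assay_names, function(a) {
    call <- table[[id]][[a]]
    if (is.null(call)) stop("missing call for ", id, " assay ", a)
    called_set(call)
  })
  if (any(vapply(p, function(x) length(x) == 1L && is.na(x), logical(1))))
    return(NULL)
  names(p) <- assay_names
  p
}

profile_key <- function(p)
  paste(vapply(names(p), function(a) paste0(a, "={", paste(p[[a]], collapse = ","), "}"),
               character(1)), collapse = " ")

profile_union <- function(p, q) {
  stopifnot(identical(names(p), names(q)))
  setNames(lapply(names(p), function(a) sort(union(p[[a]], q[[a]]))), names(p))
}

profile_diff <- function(p, q) {
  setNames(lapply(names(p), function(a) sort(setdiff(p[[a]], q[[a]]))), names(p))
}

profile_subset <- function(p, q)
  all(vapply(names(p), function(a) all(p[[a]] %in% q[[a]]), logical(1)))

profile_equal <- function(p, q) identical(profile_key(p), profile_key(q))

# ---- anchoring ------------------------------------------------------------

#' Find anchor-locus homozygotes
#'
#' An individual is listed under anchor allele `a` iff its anchor-assay call
#' is `called` with the single explanation `{a}`. Alleles observed only in
#' heterozygous combination map to an empty id vector (the rare-allele
#' situation that forces heterozygote subtraction).
#'
#' @param table a `genotype_table`.
#' @param anchor_assay anchor assay name (default `"DRB1"`).
#' @return named list: anchor allele -> character vector of individual ids.
#' @export
find_anchor_homozygotes <- function(table, anchor_assay = "DRB1") {
  seen <- character(); homs <- list()
  for (id in names(table)) {
    call <- table[[id]][[anchor_assay]]
    if (is.null(call)) stop("individual ", id, " lacks the anchor assay")
    if (call$status != "called") next
    alleles <- call$explanations[[1]]
    seen <- union(seen, alleles)
    if (length(alleles) == 1L)
      homs[[alleles]] <- c(homs[[alleles]], id)
  }
  for (a in setdiff(seen, names(homs))) homs[[a]] <- character()
  homs[order(names(homs))]
}

#' Extend an anchor allele into haplotypes from its homozygotes
#'
#' Collects the downstream-assay profiles of the anchored individuals.
#' Profiles that are set-minimal are taken as candidate haplotype
#' extensions; each observed profile must then decompose as the union of at
#' most two candidates (a DQ-heterozygous anchored individual carries two
#' haplotypes sharing the anchor allele). When the anchored individuals
#' partition into several internally consistent groups, the anchor allele is
#' split into that many haplotypes. If a profile cannot be decomposed from
#' observed candidates, its complement relative to an existing candidate is
#' derived and added (covers the case where one of the two haplotypes never
#' occurs homozygous among the anchored individuals).
#'
#' @param anchor_allele the anchor allele label.
#' @param ids anchored individual ids (from [find_anchor_homozygotes()]).
#' @param table a `genotype_table`.
#' @param assay_names downstream assay names to extend over.
#' @param min_support minimum anchored individuals required (default 4);
#'   below it the call errors ("defer") unless `allow_low_support`.
#' @param allow_low_support emit low-confidence extensions instead of
#'   deferring.
#' @return list of partial haplotypes: each a list with `anchor`, `profile`
#'   (assay -> allele labels), `support`, `provenance`, `low_confidence`.
#' @export
extend_haplotypes <- function(anchor_allele, ids, table, assay_names,
                              min_support = 4L, allow_low_support = FALSE) {
  if (length(ids) < min_support && !allow_low_support)
    stop("defer: only ", length(ids), " anchored individuals for ",
         anchor_allele, " (min_support=", min_support, ")")
  if (length(ids) == 0L)
    stop("defer: no anchored individuals for ", anchor_allele)
  profs <- list()
  for (id in ids) {
    p <- individual_profile(table, id, assay_names)
    if (!is.null(p)) profs[[id]] <- p
  }
  if (length(profs) == 0L)
    stop("defer: no usable anchored individuals for ", anchor_allele)
  keys <- vapply(profs, profile_key, character(1))
  uniq <- profs[!duplicated(keys)]
  uniq <- uniq[order(vapply(uniq, profile_key, character(1)))]
  # set-minimal profiles are candidate haplotype extensions
  minimal <- uniq[vapply(seq_along(uniq), function(i)
    !any(vapply(seq_along(uniq), function(j)
      j != i && profile_subset(uniq[[j]], uniq[[i]]) &&
        !profile_equal(uniq[[j]], uniq[[i]]), logical(1))), logical(1))]
  cands <- minimal
  decomposes <- function(p, cands) {
    for (i in seq_along(cands)) for (j in i:length(cands))
      if (profile_equal(profile_union(cands[[i]], cands[[j]]), p)) return(TRUE)
    FALSE
  }
  # derive complements for undecomposable composite profiles
  for (p in uniq) {
    if (decomposes(p, cands)) next
    for (c1 in cands) {
      if (!profile_subset(c1, p)) next
      comp <- profile_diff(p, c1)
      if (profile_equal(profile_union(c1, comp), p)) {
        cands[[length(cands) + 1L]] <- comp
        break
      }
    }
  }
  bad <- names(profs)[!vapply(profs, decomposes, logical(1), cands = cands)]
  if (length(bad))
    stop("anchored individuals with undecomposable downstream profiles for ",
         anchor_allele, ": ", paste(bad, collapse = ", "))
  ckeys <- vapply(cands, profile_key, character(1))
  cands <- cands[!duplicated(ckeys)]
  lapply(cands, function(cp) {
    support <- sum(vapply(profs, profile_equal, logical(1), q = cp))
    list(anchor = anchor_allele, profile = cp, support = support,
         provenance = "homozygote_anchored",
         low_confidence = support < min_support)
  })
}

#' Recover a rare haplotype by heterozygote subtraction
#'
#' Uses individuals heterozygous `{rare, partner}` at the anchor locus whose
#' partner allele anchors exactly one known haplotype: the partner's alleles
#' are removed from the individual's downstream calls and the residue is
#' assigned to the rare haplotype. Residues from all usable individuals are
#' pooled by union (partners sharing alleles with the rare haplotype mask
#' them in a single residue) and the pooled profile is re-verified against
#' every individual; disagreement raises a conflict naming the individuals.
#'
#' @param rare_allele anchor allele of the haplotype to recover.
#' @param table a `genotype_table`.
#' @param known list of known haplotypes (as returned by
#'   [extend_haplotypes()]), complete over `assay_names`.
#' @param assay_names downstream assay names to recover.
#' @param anchor_assay anchor assay name.
#' @return a partial haplotype (list with `anchor`, `profile`, `support`,
#'   `provenance`), or NULL when no usable individual exists.
#' @export
subtract_heterozygotes <- function(rare_allele, table, known, assay_names,
                                   anchor_assay = "DRB1") {
  by_anchor <- split(known, vapply(known, `[[`, "", "anchor"))
  usable <- list()
  for (id in names(table)) {
    call <- table[[id]][[anchor_assay]]
    if (is.null(call) || call$status != "called") next
    alleles <- call$explanations[[1]]
    obs <- individual_profile(table, id, assay_names)
    if (is.null(obs)) next
    if (length(alleles) == 1L && alleles == rare_allele) {
      # rare homozygote: degenerate subtraction, residue is its own profile
      usable[[id]] <- list(partner = NULL, observed = obs)
    } else if (length(alleles) == 2L && rare_allele %in% alleles) {
      partner_anchor <- setdiff(alleles, rare_allele)
      k <- by_anchor[[partner_anchor]]
      if (is.null(k) || length(k) != 1L) next  # partner absent or split: unusable
      if (!all(assay_names %in% names(k[[1]]$profile))) next
      partner <- k[[1]]$profile[assay_names]
      # a true partner's alleles are all present in the observed union; a
      # failed containment means the anchor maps to an uncharacterised
      # second haplotype, so the individual cannot be used
      if (!profile_subset(partner, obs)) next
      usable[[id]] <- list(partner = partner, observed = obs)
    }
  }
  if (length(usable) == 0L) return(NULL)
  empty <- setNames(lapply(assay_names, function(a) character()), assay_names)
  residue <- empty
  for (u in usable) {
    r <- if (is.null(u$partner)) u$observed else profile_diff(u$observed, u$partner)
    residue <- profile_union(residue, r)
  }
  bad <- names(usable)[!vapply(usable, function(u) {
    expected <- if (is.null(u$partner)) residue
                else profile_union(residue, u$partner)
    profile_equal(expected, u$observed)
  }, logical(1))]
  if (length(bad))
    stop("heterozygote-subtraction residues conflict for ", rare_allele,
         " across individuals: ", paste(bad, collapse = ", "))
  list(anchor = rare_allele, profile = residue, support = length(usable),
       provenance = "heterozygote_subtraction", low_confidence = FALSE)
}

# ---- full inference driver ------------------------------------------------

#' Infer the haplotype set from a genotype table
#'
#' Two-stage anchoring in the published order: anchor-locus homozygotes are
#' extended over the DQA assays (splitting shared anchor alleles), then each
#' partial haplotype is extended over the DQB assays from individuals
#' homozygous for the whole partial haplotype, with heterozygote subtraction
#' as fallback at both stages for haplotypes lacking homozygotes.
#'
#' @param table a `genotype_table`.
#' @param db the `allele_db` used for calling (resolves labels to loci).
#' @param anchor_assay anchor assay name.
#' @param stage2_assays,stage3_assays downstream assay names for the two
#'   extension stages.
#' @param min_support support threshold below which an extension is flagged
#'   low-confidence.
#' @return list with `panel` (a [haplotype_panel()] labelled H1, H2, ...),
#'   `info` (data.frame of anchor, support, provenance, low_confidence) and
#'   `haplotypes` (the raw per-haplotype records).
#' @export
infer_haplotypes <- function(table, db, anchor_assay = "DRB1",
                             stage2_assays = c("DQA1", "DQA2"),
                             stage3_assays = c("DQB1", "DQB2"),
                             min_support = 4L) {
  anchors <- find_anchor_homozygotes(table, anchor_assay)
  stage2 <- list(); deferred <- character()
  for (a in names(anchors)) {
    if (length(anchors[[a]]) >= 1L) {
      stage2 <- c(stage2, extend_haplotypes(a, anchors[[a]], table,
                                            stage2_assays,
                                            min_support = min_support,
                                            allow_low_support = TRUE))
    } else deferred <- c(deferred, a)
  }
  # resolve anchor alleles without homozygotes from heterozygotes, iterating
  # so that newly recovered haplotypes can serve as partners
  repeat {
    progress <- FALSE
    for (a in setdiff(deferred, vapply(stage2, `[[`, "", "anchor"))) {
      h <- subtract_heterozygotes(a, table, stage2, stage2_assays, anchor_assay)
      if (!is.null(h)) { stage2[[length(stage2) + 1L]] <- h; progress <- TRUE }
    }
    if (!progress) break
  }
  unresolved <- setdiff(deferred, vapply(stage2, `[[`, "", "anchor"))
  if (length(unresolved))
    warning("anchor allele(s) left unresolved: ",
            paste(unresolved, collapse = ", "))

  # stage 3: DQB from double homozygotes, with subtraction fallback
  full <- list()
  for (h in stage2) {
    dhom <- character()
    for (id in anchors[[h$anchor]]) {
      p <- individual_profile(table, id, stage2_assays)
      if (!is.null(p) && profile_equal(p, h$profile[stage2_assays]))
        dhom <- c(dhom, id)
    }
    exts <- NULL
    if (length(dhom) > 0L)
      exts <- tryCatch(
        extend_haplotypes(h$anchor, dhom, table, stage3_assays,
                          min_support = 1L, allow_low_support = TRUE),
        error = function(e) NULL)
    if (!is.null(exts)) {
      for (e in exts) {
        full[[length(full) + 1L]] <- list(
          anchor = h$anchor,
          profile = c(h$profile, e$profile),
          support = min(h$support, e$support),
          provenance = h$provenance,
          low_confidence = h$low_confidence || min(h$support, e$support) < min_support)
      }
    } else {
      full[[length(full) + 1L]] <- c(h, list(pending_stage3 = TRUE))
    }
  }
  # subtraction fallback for haplotypes with no double homozygote
  repeat {
    progress <- FALSE
    complete <- Filter(function(x) is.null(x$pending_stage3), full)
    for (i in seq_along(full)) {
      h <- full[[i]]
      if (is.null(h$pending_stage3)) next
      res <- tryCatch(
        subtract_pair_stage3(h, table, complete, stage2_assays, stage3_assays,
                             anchor_assay),
        error = function(e) NULL)
      if (!is.null(res)) {
        full[[i]] <- list(anchor = h$anchor,
                          profile = c(h$profile, res$profile),
                          support = res$support,
                          provenance = "heterozygote_subtraction",
                          low_confidence = h$low_confidence)
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  incomplete <- vapply(full, function(h) !is.null(h$pending_stage3), logical(1))
  if (any(incomplete))
    warning(sum(incomplete), " haplotype(s) could not be extended over ",
            paste(stage3_assays, collapse = "/"))
  build_inferred_panel(full, db, anchor_assay, min_support)
}

# stage-3 heterozygote subtraction for one partial haplotype: usable
# individuals are (h, k) pairs where k is a completed haplotype uniquely
# identified by its anchor, and the stage-2 observation confirms the pair
subtract_pair_stage3 <- function(h, table, complete, stage2_assays,
                                 stage3_assays, anchor_assay) {
  by_anchor <- split(complete, vapply(complete, `[[`, "", "anchor"))
  usable <- list()
  for (id in names(table)) {
    call <- table[[id]][[anchor_assay]]
    if (is.null(call) || call$status != "called") next
    alleles <- call$explanations[[1]]
    if (!(h$anchor %in% alleles) || length(alleles) != 2L) next
    partner_anchor <- setdiff(alleles, h$anchor)
    if (length(partner_anchor) == 0L) next
    k <- by_anchor[[partner_anchor]]
    if (is.null(k) || length(k) != 1L) next
    k <- k[[1]]
    obs2 <- individual_profile(table, id, stage2_assays)
    obs3 <- individual_profile(table, id, stage3_assays)
    if (is.null(obs2) || is.null(obs3)) next
    if (!profile_equal(obs2,
                       profile_union(h$profile[stage2_assays],
                                     k$profile[stage2_assays]))) next
    usable[[id]] <- list(partner = k$profile[stage3_assays], observed = obs3)
  }
  if (length(usable) == 0L) return(NULL)
  empty <- setNames(lapply(stage3_assays, function(a) character()), stage3_assays)
  residue <- empty
  for (u in usable)
    residue <- profile_union(residue, profile_diff(u$observed, u$partner))
  bad <- names(usable)[!vapply(usable, function(u)
    profile_equal(profile_union(residue, u$partner), u$observed), logical(1))]
  if (length(bad))
    stop("stage-3 subtraction residues conflict for anchor ", h$anchor,
         ": ", paste(bad, collapse = ", "))
  list(profile = residue, support = length(usable))
}

# assemble haplotype records into a labelled panel + info table
build_inferred_panel <- function(records, db, anchor_assay, min_support) {
  records <- Filter(function(h) is.null(h$pending_stage3), records)
  ord <- order(vapply(records, function(h)
    paste(h$anchor, profile_key(h$profile)), character(1)))
  records <- records[ord]
  label_locus <- function(lbl) {
    first <- strsplit(lbl, "/", fixed = TRUE)[[1]][1]
    db$locus[match(first, db$name)]
  }
  rows <- list()
  for (i in seq_along(records)) {
    h <- records[[i]]
    row <- list()
    anchor_loc <- label_locus(h$anchor)
    if (is.na(anchor_loc)) anchor_loc <- "unassigned"
    row[[anchor_loc]] <- h$anchor
    for (a in names(h$profile)) for (lbl in h$profile[[a]]) {
      loc <- label_locus(lbl)
      if (is.na(loc)) loc <- "unassigned"
      row[[loc]] <- unique(c(row[[loc]], lbl))
    }
    rows[[paste0("H", i)]] <- row
  }
  info <- data.frame(
    label = names(rows),
    anchor = vapply(records, `[[`, "", "anchor"),
    support = vapply(records, function(h) as.integer(h$support), 1L),
    provenance = vapply(records, `[[`, "", "provenance"),
    low_confidence = vapply(records, function(h) isTRUE(h$low_confidence),
                            logical(1)),
    stringsAsFactors = FALSE)
  list(panel = haplotype_panel(rows), info = info, haplotypes = records)
}

# ---- validation and summaries --------------------------------------------

all_hap_pairs <- function(labs) {
  if (length(labs) < 2L) return(cbind(labs, labs, deparse.level = 0L))
  unname(rbind(t(combn(labs, 2L)), cbind(labs, labs)))
}

#' Resolve individuals to consistent haplotype pairs
#'
#' For each individual, every unordered haplotype pair is checked: a pair is
#' consistent iff for every assay the expected product (superposition of the
#' pair's alleles, or no product on a doubly null locus) matches the
#' observation exactly.
#'
#' @param observations individual -> assay -> observation.
#' @param panel a [haplotype_panel()].
#' @param assays named list of [assay_profile()]s to check.
#' @param db an `allele_db`.
#' @return named list: individual -> character matrix (n x 2) of consistent
#'   pairs (zero rows = deviation).
#' @export
resolve_individuals <- function(observations, panel, assays, db) {
  labs <- names(panel$rows)
  pairs <- all_hap_pairs(labs)
  expected <- list()  # cache: "h1|h2|assay" -> expected observation
  out <- list()
  for (id in names(observations)) {
    ok <- matrix(character(), 0L, 2L)
    for (r in seq_len(nrow(pairs))) {
      consistent <- TRUE
      for (a in names(observations[[id]])) {
        key <- paste(pairs[r, 1L], pairs[r, 2L], a, sep = "|")
        if (is.null(expected[[key]]))
          expected[[key]] <- simulate_assay(pairs[r, ], assays[[a]], panel, db)
        e <- expected[[key]]; o <- observations[[id]][[a]]
        same <- if (is_no_product(e)) is_no_product(o)
        else if (is_no_product(o)) FALSE
        else if (isTRUE(e$length_conflict) || isTRUE(o$length_conflict))
          isTRUE(e$length_conflict) && isTRUE(o$length_conflict)
        else identical(e$codes, o$codes)
        if (!same) { consistent <- FALSE; break }
      }
      if (consistent) ok <- rbind(ok, pairs[r, ])
    }
    out[[id]] <- ok
  }
  out
}

#' Validate a haplotype set against observed genotypes
#'
#' @inheritParams resolve_individuals
#' @return data.frame of deviations (`id`, `assay`, `detail`); zero rows when
#'   every individual is explained by some haplotype pair.
#' @export
validate_haplotypes <- function(observations, panel, assays, db) {
  resolved <- resolve_individuals(observations, panel, assays, db)
  rows <- list()
  for (id in names(resolved)) {
    if (nrow(resolved[[id]]) > 0L) next
    # report which assays fail under the closest pair (fewest mismatches)
    labs <- names(panel$rows)
    pairs <- all_hap_pairs(labs)
    best_fail <- NULL
    for (r in seq_len(nrow(pairs))) {
      fails <- character()
      for (a in names(observations[[id]])) {
        e <- simulate_assay(pairs[r, ], assays[[a]], panel, db)
        o <- observations[[id]][[a]]
        same <- if (is_no_product(e)) is_no_product(o)
        else if (is_no_product(o)) FALSE
        else if (isTRUE(e$length_conflict) || isTRUE(o$length_conflict))
          isTRUE(e$length_conflict) && isTRUE(o$length_conflict)
        else identical(e$codes, o$codes)
        if (!same) fails <- c(fails, a)
      }
      if (is.null(best_fail) || length(fails) < length(best_fail))
        best_fail <- fails
    }
    rows[[id]] <- data.frame(id = id, assay = paste(best_fail, collapse = ","),
                             detail = "no consistent haplotype pair",
                             stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(id = character(), assay = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Frequencies and homozygosity from resolved individuals
#'
#' Individuals resolving to several consistent pairs contribute equal
#' fractional weight to each; unresolved individuals are excluded and
#' counted.
#'
#' @param resolved output of [resolve_individuals()].
#' @param panel the haplotype panel the pairs refer to.
#' @param anchor_locus locus used for the anchor-locus homozygosity figure.
#' @return list with `haplotype_freqs`, `allele_freqs` (per locus),
#'   `homozygosity_haplotype`, `homozygosity_anchor`, `n_resolved`,
#'   `n_unresolved`.
#' @export
haplotype_frequencies <- function(resolved, panel, anchor_locus = "DRB1") {
  labs <- names(panel$rows)
  hfreq <- setNames(numeric(length(labs)), labs)
  hom_h <- 0; hom_a <- 0; n <- 0L
  for (id in names(resolved)) {
    prs <- resolved[[id]]
    if (nrow(prs) == 0L) next
    n <- n + 1L
    w <- 1 / nrow(prs)
    for (r in seq_len(nrow(prs))) {
      h1 <- prs[r, 1L]; h2 <- prs[r, 2L]
      hfreq[h1] <- hfreq[h1] + w / 2; hfreq[h2] <- hfreq[h2] + w / 2
      if (h1 == h2) hom_h <- hom_h + w
      a1 <- haplotype_alleles(panel, h1, loci = anchor_locus, expand_groups = FALSE)
      a2 <- haplotype_alleles(panel, h2, loci = anchor_locus, expand_groups = FALSE)
      if (identical(sort(a1), sort(a2))) hom_a <- hom_a + w
    }
  }
  afreq <- list()
  for (loc in PANEL_LOCI) {
    cnt <- list()
    for (h in labs) {
      for (e in haplotype_alleles(panel, h, loci = loc, expand_groups = FALSE))
        cnt[[e]] <- (if (is.null(cnt[[e]])) 0 else cnt[[e]]) + hfreq[[h]]
    }
    if (length(cnt)) {
      v <- unlist(cnt)
      afreq[[loc]] <- v / sum(v)
    }
  }
  list(haplotype_freqs = if (n > 0L) hfreq / n else hfreq,
       allele_freqs = afreq,
       homozygosity_haplotype = if (n > 0L) hom_h / n else NA_real_,
       homozygosity_anchor = if (n > 0L) hom_a / n else NA_real_,
       n_resolved = n,
       n_unresolved = length(resolved) - n)
}
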