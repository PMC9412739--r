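#' Annotation configuration
#'
#' @param tol_ppm MS1 precursor tolerance, ppm.
#' @param tol_ms2 MS2 fragment tolerance, Da. 0.01 is the default strict
#'   mode; 0.05 is the documented loose mode for spectra whose printed
#'   fragment values carry transcription-level error.
#' @param rt_window Retention-time match window, minutes.
#' @param max_steps Maximum ladder depth (residue losses).
#' @return Named list of settings.
#' @export
annotate_config <- function(tol_ppm = 10, tol_ms2 = 0.01, rt_window = 0.5,
                            max_steps = 8L) {
  stopifnot(tol_ppm > 0, tol_ms2 > 0, rt_window >= 0, max_steps >= 1)
  list(tol_ppm = tol_ppm, tol_ms2 = tol_ms2, rt_window = rt_window,
       max_steps = as.integer(max_steps))
}

#' Score library candidates for a spectrum precursor
#'
#' Matches the precursor m/z against the theoretical `[M-H]-` and
#' `[M+HCOO]-` m/z of every library record within `tol_ppm`, with
#' deterministic ordering: |ppm|, then fewer residues, then name.
#'
#' @param spectrum An `msms_spectrum`.
#' @param library A `ginsenoside_library`.
#' @param adducts Adducts to consider.
#' @param tol_ppm MS1 tolerance, ppm.
#' @return Candidate data frame (possibly empty) as in
#'   [candidates_for_mass()].
#' @export
assign_precursor <- function(spectrum, library = load_library(),
                             adducts = c("[M-H]-", "[M+HCOO]-"),
                             tol_ppm = 10) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  candidates_for_mass(spectrum$precursor_mz, library, adducts, tol_ppm)
}

# residues that may be lost in one ladder step, in search preference order
ladder_residues <- function() {
  res <- residue_table()
  res[match(c("Hexose", "Deoxyhexose", "Pentose", "HexuronicAcid",
              "Malonyl", "Water"), res$name), ]
}

# terminal states: aglycone diagnostic ions, optionally dehydrated
# (k = 1, 2) or hydrated (k = -1); preference order k = 0, 1, 2, -1
terminal_states <- function() {
  agl <- aglycone_table()
  water <- monoisotopic_mass("H2O")
  ks <- c(0L, 1L, 2L, -1L)
  out <- expand.grid(class_name = agl$class_name, k = ks,
                     stringsAsFactors = FALSE)
  out$mz <- agl$diagnostic_mz[match(out$class_name, agl$class_name)] -
    out$k * water
  out[order(match(out$k, ks)), ]
}

#' Decompose an MS/MS spectrum into a glycosyl neutral-loss ladder
#'
#' Depth-first search over residue-mass differences. The chain starts at
#' the deprotonated precursor: for a formate precursor the first loss is
#' neutral formic acid (46.00548 Da), tried before the direct `[M-H]-`
#' reading. Each subsequent step must land on an observed fragment within
#' `tol_ms2` of the anchor minus one residue mass (anhydrohexose,
#' deoxyhexose, pentose, hexuronic acid, malonyl or water, in that
#' preference order). The chain is classified when it ends on a fragment
#' within `tol_ms2` of an aglycone diagnostic ion (`[PPD-H]-` 459.38437,
#' `[PPT-H]-` 475.37928, `[OLE-H]-` 455.35307), allowing up to two
#' dehydrations (or one hydration) of the aglycone for anhydro/ring-opened
#' ginsenosides.
#'
#' @param spectrum An `msms_spectrum` with at least one fragment.
#' @param tol_ms2 Fragment tolerance, Da.
#' @param max_steps Maximum residue losses searched.
#' @return List with `aglycone_class` (`"PPD"`, `"PPT"`, `"OLE"` or
#'   `"unclassified"`), `residue_counts` (named counts incl.
#'   `dehydration`), `steps` (data frame: `residue`, `fragment_mz`,
#'   `error`), `adduct` (the interpretation used), `anchor0` (inferred
#'   deprotonated precursor), `terminal_mz`, `complete` (every loss down
#'   to the aglycone ion observed), `cum_error`.
#' @examples
#' s <- msms_spectrum(991.5483, c(945.54101, 783.48823, 621.43679, 459.38535))
#' decompose_ladder(s)$aglycone_class
#' @export
decompose_ladder <- function(spectrum, tol_ms2 = 0.01, max_steps = 8L) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (nrow(spectrum$fragments) < 1L) stop("spectrum has no fragments")
  frags <- spectrum$fragments$mz
  res <- ladder_residues()
  terms <- terminal_states()

  nearest <- function(target) {
    d <- abs(frags - target)
    i <- which.min(d)
    if (d[i] <= tol_ms2) frags[i] else NA_real_
  }

  solutions <- list()
  best_partial <- NULL

  dfs <- function(anchor, steps, cum_err, observed) {
    # terminal: observed anchor sitting on an aglycone diagnostic ion
    if (observed) {
      hit <- which(abs(anchor - terms$mz) <= tol_ms2)
      if (length(hit)) {
        h <- hit[1]
        solutions[[length(solutions) + 1L]] <<- list(
          class = terms$class_name[h], k = terms$k[h], steps = steps,
          cum_err = cum_err + abs(anchor - terms$mz[h]),
          terminal_mz = anchor)
      }
    }
    if (is.null(best_partial) || nrow(steps) > nrow(best_partial$steps) ||
        (nrow(steps) == nrow(best_partial$steps) &&
         cum_err < best_partial$cum_err)) {
      best_partial <<- list(steps = steps, cum_err = cum_err,
                            terminal_mz = anchor)
    }
    if (nrow(steps) >= max_steps) return()
    for (j in seq_len(nrow(res))) {
      f <- nearest(anchor - res$mass[j])
      if (!is.na(f)) {
        err <- abs(f - (anchor - res$mass[j]))
        dfs(f, rbind(steps, data.frame(residue = res$name[j],
                                       fragment_mz = f, error = err)),
            cum_err + err, observed = TRUE)
      }
    }
  }

  empty_steps <- data.frame(residue = character(0), fragment_mz = numeric(0),
                            error = numeric(0))
  interp <- list()
  for (ad in c("[M+HCOO]-", "[M-H]-")) {
    # formate precursors collapse to [M-H]- by loss of neutral HCOOH
    anchor0 <- if (ad == "[M+HCOO]-") {
      spectrum$precursor_mz - FORMIC_ACID_MASS
    } else {
      spectrum$precursor_mz
    }
    solutions <- list()
    best_partial <- NULL
    snapped <- nearest(anchor0)
    observed0 <- !is.na(snapped)
    start <- if (observed0) snapped else anchor0
    dfs(start, empty_steps, if (observed0) abs(snapped - anchor0) else 0,
        observed0)
    sol <- NULL
    if (length(solutions)) {
      ord <- order(vapply(solutions, function(s) nrow(s$steps) + abs(s$k),
                          numeric(1)),
                   vapply(solutions, function(s) s$cum_err, numeric(1)))
      sol <- solutions[[ord[1]]]
    }
    interp[[ad]] <- list(adduct = ad, anchor0 = anchor0, solution = sol,
                         partial = best_partial)
  }

  pick <- if (!is.null(interp[["[M+HCOO]-"]]$solution)) {
    interp[["[M+HCOO]-"]]
  } else if (!is.null(interp[["[M-H]-"]]$solution)) {
    interp[["[M-H]-"]]
  } else {
    # no terminal under either reading: keep the longer partial chain
    a <- interp[["[M+HCOO]-"]]; b <- interp[["[M-H]-"]]
    if (nrow(b$partial$steps) > nrow(a$partial$steps)) b else a
  }

  counts <- stats::setNames(integer(6),
                            c("Hexose", "Deoxyhexose", "Pentose",
                              "HexuronicAcid", "Malonyl", "dehydration"))
  if (!is.null(pick$solution)) {
    s <- pick$solution
    tab <- table(s$steps$residue)
    water_steps <- if ("Water" %in% names(tab)) tab[["Water"]] else 0L
    for (nm in setdiff(names(tab), "Water")) counts[nm] <- tab[[nm]]
    counts["dehydration"] <- s$k + water_steps
    list(aglycone_class = s$class, residue_counts = counts,
         steps = s$steps, adduct = pick$adduct, anchor0 = pick$anchor0,
         terminal_mz = s$terminal_mz, complete = TRUE,
         cum_error = s$cum_err)
  } else {
    p <- pick$partial
    tab <- table(p$steps$residue)
    water_steps <- if ("Water" %in% names(tab)) tab[["Water"]] else 0L
    for (nm in setdiff(names(tab), "Water")) counts[nm] <- tab[[nm]]
    counts["dehydration"] <- water_steps
    list(aglycone_class = "unclassified", residue_counts = counts,
         steps = p$steps, adduct = pick$adduct, anchor0 = pick$anchor0,
         terminal_mz = p$terminal_mz, complete = FALSE,
         cum_error = p$cum_err)
  }
}

#' Classify an MS/MS spectrum
#'
#' Combines precursor matching against the ginsenoside library
#' ([assign_precursor()]) with de-novo neutral-loss ladder decomposition
#' ([decompose_ladder()]). A library record is accepted as
#' `standard_match` when it agrees with the precursor mass, the
#' retention time (when both spectrum and record carry one, within
#' `rt_window`), and — if the ladder classified — the aglycone class.
#' Without a library hit the ladder result is reported alone
#' (`ladder_complete` / `ladder_partial`); with only a mass hit the
#' record's class is reported as `mass_only`. Contradictory precursor
#' and ladder evidence is flagged (`conflict = TRUE`) with both
#' hypotheses retained, never silently dropped.
#'
#' @param spectrum An `msms_spectrum`.
#' @param library A `ginsenoside_library`.
#' @param config See [annotate_config()].
#' @return A `ginsenoside_annotation` list.
#' @examples
#' s <- msms_spectrum(991.5483, c(945.54101, 783.48823, 621.43679, 459.38535),
#'                    retention_time = 28.47)
#' classify(s)$aglycone_class
#' @export
classify <- function(spectrum, library = load_library(),
                     config = annotate_config()) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  cands <- assign_precursor(spectrum, library, tol_ppm = config$tol_ppm)
  ladder <- decompose_ladder(spectrum, tol_ms2 = config$tol_ms2,
                             max_steps = config$max_steps)

  rt_known <- !is.na(spectrum$retention_time)
  if (nrow(cands)) {
    cands$rt_ok <- rt_known & !is.na(cands$rt) &
      abs(cands$rt - spectrum$retention_time) <= config$rt_window
    cands$d_rt <- ifelse(cands$rt_ok,
                         abs(cands$rt - spectrum$retention_time), Inf)
    cands$ladder_match <- FALSE
    if (ladder$complete) {
      for (i in seq_len(nrow(cands))) {
        rc <- residue_counts(cands[i, ])
        cands$ladder_match[i] <- cands$class[i] == ladder$aglycone_class &&
          all(rc[names(ladder$residue_counts)] == ladder$residue_counts)
      }
    }
    # prefer RT-confirmed, then ladder-corroborated, then closest mass
    ord <- order(!cands$rt_ok, !cands$ladder_match, cands$d_rt,
                 abs(cands$ppm), cands$n_residues, cands$name)
    cands <- cands[ord, , drop = FALSE]
  }

  top <- if (nrow(cands)) cands[1, , drop = FALSE] else NULL
  conflict <- FALSE

  if (!is.null(top)) {
    record_counts <- residue_counts(top)[names(ladder$residue_counts)]
    comp_agrees <- ladder$complete &&
      top$class == ladder$aglycone_class &&
      all(record_counts == ladder$residue_counts)
    class_conflicts <- ladder$complete &&
      !any(cands$class == ladder$aglycone_class)
    if (class_conflicts) {
      conflict <- TRUE
      primary <- if (any(cands$rt_ok)) top$class else ladder$aglycone_class
      confidence <- if (any(cands$rt_ok)) "mass_only" else "ladder_complete"
      counts <- if (any(cands$rt_ok)) record_counts else ladder$residue_counts
    } else if (comp_agrees) {
      primary <- top$class
      counts <- ladder$residue_counts
      confidence <- if (top$rt_ok) "standard_match" else "ladder_complete"
    } else if (ladder$complete) {
      # ladder classified; some candidate shares the class but not this one's
      # exact composition (isomer bookkeeping) - keep the record identity
      primary <- top$class
      counts <- if (top$ladder_match) ladder$residue_counts else record_counts
      confidence <- if (top$rt_ok) "standard_match" else "ladder_complete"
    } else {
      primary <- top$class
      counts <- record_counts
      confidence <- if (top$rt_ok) "standard_match" else "mass_only"
    }
    matched <- top$name
    adduct <- top$adduct
    ppm <- top$ppm
  } else if (ladder$complete) {
    primary <- ladder$aglycone_class
    counts <- ladder$residue_counts
    confidence <- "ladder_complete"
    matched <- NA_character_; adduct <- ladder$adduct; ppm <- NA_real_
  } else {
    primary <- "unclassified"
    counts <- ladder$residue_counts
    confidence <- "ladder_partial"
    matched <- NA_character_; adduct <- ladder$adduct; ppm <- NA_real_
  }

  structure(list(
    title = spectrum$title,
    precursor_mz = spectrum$precursor_mz,
    retention_time = spectrum$retention_time,
    aglycone_class = primary,
    residue_counts = counts,
    matched_record = matched,
    adduct = adduct,
    precursor_ppm = ppm,
    ladder = ladder$steps,
    ladder_class = ladder$aglycone_class,
    ladder_complete = ladder$complete,
    confidence = confidence,
    conflict = conflict,
    candidates = if (nrow(cands)) cands$name else character(0)
  ), class = "ginsenoside_annotation")
}

#' @export
print.ginsenoside_annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s  precursor %.5f  class %s  (%s%s)\n",
              if (is.na(x$matched_record)) "de novo" else x$matched_record,
              x$precursor_mz, x$aglycone_class, x$confidence,
              if (x$conflict) ", CONFLICT" else ""))
  invisible(x)
}

#' Annotate a batch of spectra
#'
#' Order-preserving; per-spectrum errors are collected, never abort the
#' batch.
#'
#' @param spectra List of `msms_spectrum`.
#' @param library A `ginsenoside_library`.
#' @param config See [annotate_config()].
#' @return List with `annotations` (one per spectrum; failed ones carry
#'   class `annotation_error`), and `summary` — named counts of
#'   PPD/PPT/OLE/unclassified assignments.
#' @export
annotate_batch <- function(spectra, library = load_library(),
                           config = annotate_config()) {
  anns <- lapply(spectra, function(s) {
    tryCatch(classify(s, library, config),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "annotation_error"))
  })
  classes <- vapply(anns, function(a) {
    if (inherits(a, "annotation_error")) "error" else a$aglycone_class
  }, character(1))
  lv <- c("PPD", "PPT", "OLE", "unclassified", "error")
  list(annotations = anns,
       summary = table(factor(classes, levels = lv)))
}

#' Write annotations as JSON lines
#'
#' One JSON object per spectrum, floats at 6 significant decimals.
#'
#' @param annotations List of `ginsenoside_annotation` (or the
#'   `annotations` element of [annotate_batch()] output).
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in annotations) {
    rec <- if (inherits(a, "annotation_error")) {
      list(error = a$message)
    } else {
      list(title = a$title, precursor_mz = round(a$precursor_mz, 6),
           retention_time = a$retention_time,
           aglycone_class = a$aglycone_class,
           residue_counts = as.list(a$residue_counts),
           matched_record = a$matched_record, adduct = a$adduct,
           precursor_ppm = if (is.na(a$precursor_ppm)) NULL
                           else round(a$precursor_ppm, 6),
           confidence = a$confidence, conflict = a$conflict)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}
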