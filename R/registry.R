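#' @title PPH concept registry
#' @description The registry is the machine-readable list of the 24
#'   postpartum-hemorrhage-related concepts the pipeline extracts: 23 binary
#'   concepts (conditions, drugs, procedures, transfusion products) plus one
#'   measurement concept, estimated blood loss (EBL). Each concept carries an
#'   ordered list of prompt templates for generative backends and a set of
#'   case-insensitive regular expressions for the pattern baseline.
#' @name registry
NULL

# Placeholder token that prompt templates must contain exactly once.
PROMPT_PLACEHOLDER <- "<note>"

#' Construct a prompt template
#'
#' @param template_text Prompt text containing the chunk placeholder
#'   `"<note>"` exactly once.
#' @param answer_mode `"yes_no"` for binary concepts, `"extract"` for the
#'   measurement concept.
#' @return A list of class `pph_prompt`.
#' @export
prompt_template <- function(template_text, answer_mode = c("yes_no", "extract")) {
  answer_mode <- match.arg(answer_mode)
  n <- placeholder_count(template_text)
  if (n != 1L) {
    stop("prompt template must contain the placeholder '", PROMPT_PLACEHOLDER,
         "' exactly once (found ", n, ")")
  }
  structure(list(template_text = template_text, answer_mode = answer_mode),
            class = "pph_prompt")
}

placeholder_count <- function(text) {
  lengths(regmatches(text, gregexpr(PROMPT_PLACEHOLDER, text, fixed = TRUE)))
}

#' Render a prompt for one text chunk
#'
#' Replaces the placeholder with `chunk_text` in a single pass: if the chunk
#' itself contains the placeholder literal it is inserted verbatim, never
#' re-substituted.
#'
#' @param template A [prompt_template()].
#' @param chunk_text Non-empty chunk text.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(template, chunk_text) {
  stopifnot(inherits(template, "pph_prompt"))
  if (!is.character(chunk_text) || length(chunk_text) != 1L || !nzchar(chunk_text)) {
    stop("chunk_text must be a non-empty string")
  }
  if (placeholder_count(template$template_text) != 1L) {
    stop("template does not contain the placeholder exactly once")
  }
  sub(PROMPT_PLACEHOLDER, chunk_text, template$template_text, fixed = TRUE)
}

#' Construct a concept specification
#'
#' @param concept_id Slug identifier (unique within a registry).
#' @param display_name Human-readable name.
#' @param kind `"binary"` or `"measurement"`.
#' @param prompts List of [prompt_template()] objects (non-empty, ordered;
#'   multi-prompt concepts are "chained": any positive prompt makes the
#'   concept positive).
#' @param patterns Character vector of case-insensitive regular expressions
#'   (PCRE) for the pattern baseline.
#' @param description Free-text intent of the concept and its patterns.
#' @return A list of class `pph_concept`.
#' @export
concept_spec <- function(concept_id, display_name, kind = c("binary", "measurement"),
                         prompts, patterns, description = "") {
  kind <- match.arg(kind)
  stopifnot(length(prompts) >= 1L)
  for (p in prompts) {
    stopifnot(inherits(p, "pph_prompt"))
    want <- if (kind == "binary") "yes_no" else "extract"
    if (p$answer_mode != want) {
      stop("concept ", concept_id, ": answer_mode '", p$answer_mode,
           "' inconsistent with kind '", kind, "'")
    }
  }
  structure(list(concept_id = concept_id, display_name = display_name,
                 kind = kind, prompts = prompts,
                 patterns = as.character(patterns), description = description),
            class = "pph_concept")
}

yn_prompt <- function(subject) {
  prompt_template(paste0(
    "Answer the following yes/no question. Does the following discharge summary mention ",
    subject, " during the current delivery? note: <note>"), "yes_no")
}

#' The built-in registry of 24 PPH-related concepts
#'
#' Prompt texts for `pph_mention`, `methylergonovine`, `estimated_blood_loss`
#' and the three chained `accreta_spectrum` prompts are the published example
#' prompts; the remaining prompts are authored in the same grammar. Pattern
#' sets are authored to cover canonical names, common abbreviations
#' (`d&c`, `pph`, `prbc`, `ffp`), and frequent variants; each spec's
#' `description` states the patterns' intent.
#'
#' @return A named list of [concept_spec()]s, length 24.
#' @export
builtin_registry <- function() {
  specs <- list(
    concept_spec(
      "laceration", "Laceration", "binary",
      list(yn_prompt("a perineal, cervical, or vaginal laceration or tear")),
      c("lacerat", "sulcal tear", "perineal tear", "cervical tear"),
      "Obstetric lacerations/tears; stem 'lacerat' covers laceration(s)/lacerated."),
    concept_spec(
      "bakri_balloon", "Bakri balloon", "binary",
      list(yn_prompt("placement of a Bakri balloon")),
      c("bakri"),
      "Intrauterine balloon tamponade; the device name is specific."),
    concept_spec(
      "cesarean_delivery", "Cesarean delivery", "binary",
      list(yn_prompt("a cesarean delivery")),
      c("cesarean", "c-section", "\\bc/s\\b"),
      "Cesarean mode of delivery, including the c-section abbreviation."),
    concept_spec(
      "methylergonovine", "Methylergonovine", "binary",
      list(prompt_template(
        paste0("Answer the following yes/no question. Does the following ",
               "discharge summary mention the drug methergine (methylergonovine)? ",
               "note: <note>"), "yes_no")),
      c("methergine", "methylergonovine"),
      "Second-line uterotonic; brand and generic names."),
    concept_spec(
      "placenta_previa", "Placenta previa", "binary",
      list(yn_prompt("placenta previa")),
      c("previa"),
      "Placenta previa (complete/marginal/low-lying previa all contain 'previa')."),
    concept_spec(
      "fresh_frozen_plasma", "Fresh frozen plasma", "binary",
      list(yn_prompt("transfusion of fresh frozen plasma (FFP)")),
      c("fresh frozen plasma", "\\bffp\\b"),
      "FFP transfusion; abbreviation guarded by word boundaries."),
    concept_spec(
      "carboprost", "Carboprost", "binary",
      list(yn_prompt("administration of carboprost (Hemabate)")),
      c("carboprost", "hemabate"),
      "Prostaglandin uterotonic; brand and generic names."),
    concept_spec(
      "misoprostol_uterotonic", "Misoprostol as a uterotonic", "binary",
      list(yn_prompt("administration of misoprostol to treat uterine bleeding or hemorrhage"),
           yn_prompt("administration of misoprostol as a uterotonic medication")),
      c("misoprostol.{0,40}(uterotonic|hemorrhage|uterine bleeding|\\baton)",
        "cytotec.{0,40}(uterotonic|hemorrhage|uterine bleeding|\\baton)",
        "rectal misoprostol"),
      paste("Misoprostol given for bleeding/atony, not for cervical ripening or",
            "labor induction; patterns require a bleeding/uterotonic context",
            "within 40 characters, which excludes the induction use.")),
    concept_spec(
      "hysterectomy", "Hysterectomy", "binary",
      list(yn_prompt("a peripartum hysterectomy")),
      c("hysterectomy"),
      "Peripartum/supracervical/total hysterectomy."),
    concept_spec(
      "oleary_sutures", "O'Leary sutures", "binary",
      list(yn_prompt("placement of O'Leary sutures or uterine artery ligation stitches")),
      c("o.{0,2}leary"),
      "O'Leary uterine artery ligation sutures; apostrophe/space variants."),
    concept_spec(
      "uterine_atony", "Uterine atony", "binary",
      list(yn_prompt("uterine atony")),
      c("uterine atony", "atonic", "\\batony\\b"),
      "Inadequate uterine tone: 'uterine atony', 'atonic uterus', bare 'atony'."),
    concept_spec(
      "retained_products", "Retained products of conception", "binary",
      list(yn_prompt("retained products of conception or retained placental tissue")),
      c("retained (products|poc|placenta|placental)"),
      "Retained products of conception incl. the POC abbreviation."),
    concept_spec(
      "pph_mention", "Direct mention of PPH", "binary",
      list(prompt_template(
        paste0("Answer the following yes/no question. Does the following ",
               "discharge summary mention postpartum hemorrhage (PPH) during ",
               "the current delivery? note: <note>"), "yes_no")),
      c("postpartum hemorrhage", "post-partum hemorrhage", "\\bpph\\b"),
      "Explicit naming of the complication, spelled out or abbreviated."),
    concept_spec(
      "prbc", "Packed red blood cells", "binary",
      list(yn_prompt("transfusion of packed red blood cells (pRBC)")),
      c("packed red blood cells", "packed cells", "\\bprbc"),
      "Red-cell transfusion; 'prbc' stem also matches 'pRBCs'."),
    concept_spec(
      "abruption", "Abruption of the placenta", "binary",
      list(yn_prompt("abruption of the placenta")),
      c("abruption"),
      "Placental abruption."),
    concept_spec(
      "coagulation_disorders", "Coagulation disorders", "binary",
      list(yn_prompt("disseminated intravascular coagulation (DIC)"),
           yn_prompt("a coagulation disorder with increased risk of bleeding"),
           yn_prompt("a coagulopathy")),
      c("disseminated intravascular", "coagulopathy", "\\bdic\\b",
        "coagulation disorder"),
      paste("Coagulation disorders with increased bleeding risk; chained",
            "prompts cover DIC, named disorders, and generic coagulopathy.")),
    concept_spec(
      "cryoprecipitate", "Cryoprecipitate", "binary",
      list(yn_prompt("transfusion of cryoprecipitate")),
      c("cryoprecipitate", "\\bcryo\\b"),
      "Cryoprecipitate transfusion incl. the 'cryo' short form."),
    concept_spec(
      "dilation_curettage", "Dilation and curettage", "binary",
      list(yn_prompt("a dilation and curettage (D&C) procedure")),
      c("dilat(at)?ion and curettage", "d\\s?&\\s?c\\b", "curettage"),
      "D&C incl. the ampersand abbreviation and 'sharp curettage'."),
    concept_spec(
      "platelets", "Platelets", "binary",
      list(yn_prompt("transfusion of platelets")),
      c("platelet"),
      "Platelet transfusion."),
    concept_spec(
      "accreta_spectrum", "Placenta accreta spectrum", "binary",
      list(yn_prompt("placenta percreta"),
           yn_prompt("placenta increta"),
           yn_prompt("placenta accreta")),
      c("percreta", "increta", "accreta"),
      paste("Placenta accreta spectrum; three chained prompts, one per depth",
            "of invasion, any positive marks the spectrum concept.")),
    concept_spec(
      "manual_extraction_placenta", "Manual extraction of placenta", "binary",
      list(yn_prompt("manual extraction or manual removal of the placenta")),
      c("manual extraction", "manual removal", "(delivered|extracted|removed) manually"),
      "Manual placenta delivery; active and passive phrasings."),
    concept_spec(
      "pph_surgical", "PPH due to surgical causes", "binary",
      list(yn_prompt("bleeding from a surgical source such as the uterine artery"),
           yn_prompt("hemorrhage caused by surgical injury")),
      c("uterine artery", "surgical (bleeding|source|injury)",
        "bleeding from the (surgical|hysterotomy)"),
      paste("Hemorrhage attributed to surgical injury (e.g. uterine artery",
            "damage); chained prompts for vessel and generic surgical causes.")),
    concept_spec(
      "uterine_rupture", "Uterine rupture", "binary",
      list(yn_prompt("uterine rupture")),
      c("uterine rupture", "ruptured uterus"),
      paste("Uterine rupture; patterns require the uterine qualifier so that",
            "artificial/spontaneous rupture of membranes does not match.")),
    concept_spec(
      "estimated_blood_loss", "Estimated blood loss", "measurement",
      list(prompt_template(
        paste0("Extract the estimated blood loss (EBL) in the following ",
               "discharge summary. If you can't find the answer, please ",
               "respond \"unanswerable\". note: <note>"), "extract")),
      c(paste0("(?:estimated blood loss|\\bebl\\b|blood loss)[^0-9\\n]{0,20}",
               "([0-9]+(?:[\\.,][0-9]+)?\\s?(?:ml|cc|l\\b)?)")),
      paste("EBL value extraction: a number (with optional unit) within 20",
            "characters of an EBL cue; the capture group is the returned",
            "segment.")))
  names(specs) <- vapply(specs, `[[`, character(1), "concept_id")
  specs
}

#' Validate a concept registry
#'
#' Checks the registry invariants: unique ids, non-empty prompt lists,
#' placeholder present exactly once per prompt, answer modes consistent with
#' concept kinds, every pattern compiles, and exactly one measurement concept.
#'
#' @param registry A list of [concept_spec()]s.
#' @return Character vector of violations (empty when valid).
#' @export
validate_registry <- function(registry) {
  violations <- character(0)
  ids <- vapply(registry, `[[`, character(1), "concept_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    violations <- c(violations, paste0("duplicate concept_id: ", dup))
  }
  n_meas <- sum(vapply(registry, function(s) s$kind == "measurement", logical(1)))
  if (n_meas != 1L) {
    violations <- c(violations,
                    sprintf("expected exactly 1 measurement concept, found %d", n_meas))
  }
  for (s in registry) {
    if (length(s$prompts) == 0L) {
      violations <- c(violations, paste0(s$concept_id, ": no prompts"))
    }
    for (p in s$prompts) {
      if (placeholder_count(p$template_text) != 1L) {
        violations <- c(violations, paste0(s$concept_id, ": prompt placeholder count != 1"))
      }
      want <- if (s$kind == "binary") "yes_no" else "extract"
      if (p$answer_mode != want) {
        violations <- c(violations,
                        paste0(s$concept_id, ": answer_mode inconsistent with kind"))
      }
    }
    for (pat in s$patterns) {
      ok <- tryCatch({
        grepl(pat, "probe text", perl = TRUE, ignore.case = TRUE)
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        violations <- c(violations,
                        paste0(s$concept_id, ": pattern does not compile: ", pat))
      }
    }
  }
  violations
}

#' Serialize a registry to a YAML config file
#'
#' Users can add or edit concepts without code changes; [read_registry()]
#' round-trips the file back into concept specs.
#'
#' @param registry A list of [concept_spec()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  obj <- lapply(unname(registry), function(s) {
    list(concept_id = s$concept_id, display_name = s$display_name,
         kind = s$kind,
         prompts = lapply(s$prompts, function(p) {
           list(template_text = p$template_text, answer_mode = p$answer_mode)
         }),
         patterns = as.list(s$patterns), description = s$description)
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a registry from a YAML config file
#' @param path Path written by [write_registry()] (or hand-authored in the
#'   same shape).
#' @return A named list of [concept_spec()]s.
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- lapply(obj, function(s) {
    concept_spec(s$concept_id, s$display_name, s$kind,
                 prompts = lapply(s$prompts, function(p) {
                   prompt_template(p$template_text, p$answer_mode)
                 }),
                 patterns = unlist(s$patterns), description = s$description)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "concept_id")
  specs
}
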