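# Merged-schema edge-type strings (naming-grammar regression corpus).
# hetnet seed renames (old compound-abbreviated and new chemical-abbreviated forms)
CAUSES_CcSE
CAUSES_CHcSE
PALLIATES_CpD
PALLIATES_CHpD
TREATS_CtD
TREATS_CHtD
BINDS_CbG
BINDS_CHbG
DOWNREGULATES_CdG
DOWNREGULATES_CHdG
# disease ontology
IS_A_DiaD
# gene-disease / phenotype-gene associations
ASSOCIATES_PaG
ASSOCIATES_DaG
# pathways
PARTICIPATES_IN_GpiPW
# protein layer
INTERACTS_IiP
INTERACTS_PiI
PRODUCES_GpP
# GO hierarchy
IS_A_BPiaBP
IS_A_CCiaCC
IS_A_MFiaMF
# interaction subcellular location
MIGHT_SUBCELLULAR_LOCATES_ImslCC
# pathway-pathway
PRECEDING_REACTION_PWprPW
NORMAL_PATHWAY_PWnpPW
OCCURS_IN_PWoiPW
HAS_ENCAPSULATED_EVENT_PWheePW
# reaction-like events
IS_NORMAL_REACTION_RLEinrRLE
PRECEDING_REACTION_RLEprRLE
HAS_EFFECT_ON_RLEheoRLE
REVERSE_REACTION_RLErrRLE
PRECEDING_REACTION_PWprRLE
PRECEDING_REACTION_RLEprPW
PARTICIPATES_IN_PWpiRLE
IN_COMPARTMENT_RLEicCC
OCCURS_IN_PWoiBP
OCCURS_IN_RLEoiBP
IN_COMPARTMENT_PWicCC
LEADS_TO_DISEASE_RLEltdD
LEADS_TO_PWltD
# variants
HAS_GhV
HAS_HhGV
HAS_GThH
HAS_GThGV
# drugs
HAS_ChPR
COMBINATION_CAUSES_ADR_VccaCH
PART_OF_CpoSA
INTERACTS_CiC
RESEMBLES_CrC
# disease-symptom
PRESENTS_DpS
# chemical-gene
BINDS_GbCH
ASSOCIATES_CHaG
ASSOCIATES_GaCH
UPREGULATES_GuCH
UPREGULATES_CHuG
DOWNREGULATES_GdCH
AFFECTS_DEGENERATION_GadCH
DECREASES_DEGENERATION_CHddG
INCREASES_DEGENERATION_CHidG
INCREASES_DEGENERATION_GidCH
IS_ACTIVE_IN_METABOLISM_CHiaimG
IS_ACTIVE_IN_METABOLISM_GiaimCH
IS_ACTIVE_ON_CELLULAR_LEVEL_CHiaoclG
IS_ACTIVE_ON_CELLULAR_LEVEL_GiaoclCH
IS_ACTIVE_ON_DNA_OR_RNA_LEVEL_CHiaodorlG
IS_ACTIVE_ON_POLYPEPTIDE_LEVEL_CHiaoplG
IS_ACTIVE_ON_POLYPEPTIDE_LEVEL_GiaoplCH
# chemical-GO
ASSOCIATES_CHaBP
ASSOCIATES_CHaCC
ASSOCIATES_CHaMF
DECREASES_CHdBP
DECREASES_CHdCC
DECREASES_CHdMF
INCREASES_CHiBP
INCREASES_CHiCC
INCREASES_CHiMF
# chemical-disease
INDUCES_CHiD
# chemical-protein
BINDS_CHbP
BINDS_PbCH
ASSOCIATES_CHaP
ASSOCIATES_PaCH
UPREGULATES_CHuP
UPREGULATES_PuCH
DOWNREGULATES_CHdP
DOWNREGULATES_PdCH
AFFECTS_DEGENERATION_CHadP
AFFECTS_DEGENERATION_PadCH
DECREASES_DEGENERATION_CHddP
DECREASES_DEGENERATION_PddCH
INCREASES_DEGENERATION_CHidP
INCREASES_DEGENERATION_PidCH
IS_ACTIVE_IN_METABOLISM_CHiaimP
IS_ACTIVE_IN_METABOLISM_PiaimCH
IS_ACTIVE_ON_CELLULAR_LEVEL_CHiaoclP
IS_ACTIVE_ON_CELLULAR_LEVEL_PiaoclCH
IS_ACTIVE_ON_DNA_OR_RNA_LEVEL_CHiaodorlP
IS_ACTIVE_ON_DNA_OR_RNA_LEVEL_PiaodorlCH
IS_ACTIVE_ON_POLYPEPTIDE_LEVEL_CHiaoplP
IS_ACTIVE_ON_POLYPEPTIDE_LEVEL_PiaoplCH
# pharmacological classes
INCLUDES_CiPC
INCLUDES_PCiPC
CONTRAINDICATES_CHcCH
CONTRAINDICATES_CHcPC
CONTRAINDICATES_CHcD
TREATS_PCtD
HAS_ACTIVE_METABOLITE_CHhamCH
HAS_CHEMICAL_STRUCTURE_CHhcsCH
HAS_CHEMICAL_STRUCTURE_PChcsCH
HAS_INGREDIENT_CHhiCH
INCLUDES_PCiCH
MAY_DIAGNOSES_CHmdD
MAY_DIAGNOSES_PCmdD
METABOLIZES_PCmCH
PREVENTS_CHpD
PREVENTS_PCpD
# treatments and reaction participants
TREATS_CHtT
TREATS_TtD
IS_LOCALIZED_IN_TiliCC
HAS_INPUT_RLEhiCH
HAS_OUTPUT_RLEhoCH
IS_INPUT_OF_PiioRLE
# variant-chemical associations
ASSOCIATES_TO_DOSAGE_VatdCH
ASSOCIATES_TO_EFFICACY_DOSAGE_VatedCH
ASSOCIATES_TO_EFFICACY_METABOLISM_PK_DOSAGE_VatempdCH
ASSOCIATES_TO_EFFICACY_TOXICITY_ADR_DOSAGE_VatetadCH
ASSOCIATES_TO_EFFICACY_VateCH
ASSOCIATES_TO_METABOLISM_PK_DOSAGE_VatmpdCH
ASSOCIATES_TO_METABOLISM_PK_TOXICITY_ADR_VatmptaCH
ASSOCIATES_TO_METABOLISM_PK_VatmpCH
ASSOCIATES_TO_TOXICITY_ADR_DOSAGE_VattadCH
ASSOCIATES_TO_TOXICITY_ADR_EFFICACY_VattaeCH
ASSOCIATES_TO_TOXICITY_ADR_VattaCH
ASSOCIATES_TO_TOXICITY_VattCH
ASSOCIATES_VaCH
# chemical-chemical and ATC classes
ASSOCIATES_CHaCH
BINDS_CHbCH
DEGENERATES_CHdCH
DOWNREGULATES_CHdCH
IS_ACTIVE_IN_METABOLISM_CHiaimCH
REGULATES_CHrCH
IS_ACTIVE_ON_POLYPEPTIDE_LEVEL_CHiaoplCH
BELONGS_TO_CHbtPC
BELONGS_TO_PCbtPC
# drug-target
DEGENERATES_CHdP
INHIBITS_CHiP
IS_ACTIVE_AS_ANTIBODY_CHiaaaP
REGULATES_CHrP
# adverse events
MIGHT_CAUSES_CHmcSE
MIGHT_INDUCES_CHmiD
# annotation edge nodes
ASSOCIATES_CAaG
ASSOCIATES_CAaV
ASSOCIATES_CAaCH
ASSOCIATES_CAaPT
ASSOCIATES_CAaPC
ASSOCIATES_VAaG
ASSOCIATES_VAaV
ASSOCIATES_VAaCH
ASSOCIATES_VAaH
ASSOCIATES_VAaPC
HAS_EVIDENCE_CAheVA
# equal-meaning and allele links
EQUAL_DeSE
EQUAL_DeS
EQUAL_PTeSE
EQUAL_SeSE
IS_ALLEL_OF_ViaoV
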