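# Graph data model for clinical proteomics projects.
# 36 node labels and 47 relationship type names; a relationship type may be
# permitted between several (source, target) label pairs (e.g. HAS_PARENT
# inside every ontology-backed label).
node_labels:
  - Amino_acid_sequence
  - Analytical_sample
  - Biological_process
  - Biological_sample
  - Cellular_component
  - Chromosome
  - Clinical_variable
  - Clinically_relevant_variant
  - Complex
  - Disease
  - Drug
  - Experimental_factor
  - Food
  - Functional_region
  - GWAS_study
  - Gene
  - Known_variant
  - Metabolite
  - Modification
  - Modified_protein
  - Molecular_function
  - Pathway
  - Peptide
  - Phenotype
  - Project
  - Protein
  - Protein_structure
  - Publication
  - Side_effect
  - Subject
  - Timepoint
  - Tissue
  - Transcript
  - Transcription_factor
  - Units
  - User
relationships:
  - {type: HAS_PARENT, source: Disease, target: Disease}
  - {type: HAS_PARENT, source: Tissue, target: Tissue}
  - {type: HAS_PARENT, source: Biological_process, target: Biological_process}
  - {type: HAS_PARENT, source: Molecular_function, target: Molecular_function}
  - {type: HAS_PARENT, source: Cellular_component, target: Cellular_component}
  - {type: HAS_PARENT, source: Phenotype, target: Phenotype}
  - {type: HAS_PARENT, source: Clinical_variable, target: Clinical_variable}
  - {type: HAS_PARENT, source: Modification, target: Modification}
  - {type: HAS_PARENT, source: Food, target: Food}
  - {type: HAS_PARENT, source: Experimental_factor, target: Experimental_factor}
  - {type: HAS_PARENT, source: Units, target: Units}
  - {type: ASSOCIATED_WITH, source: Protein, target: Disease}
  - {type: ASSOCIATED_WITH, source: Gene, target: Disease}
  - {type: ASSOCIATED_WITH, source: Metabolite, target: Disease}
  - {type: ASSOCIATED_WITH, source: Clinical_variable, target: Disease}
  - {type: ASSOCIATED_WITH, source: Protein, target: Biological_process}
  - {type: ASSOCIATED_WITH, source: Protein, target: Molecular_function}
  - {type: ASSOCIATED_WITH, source: Protein, target: Cellular_component}
  - {type: HAS_QUANTIFIED_PROTEIN, source: Analytical_sample, target: Protein}
  - {type: HAS_QUANTIFIED_PEPTIDE, source: Analytical_sample, target: Peptide}
  - {type: HAS_QUANTIFIED_MODIFIED_PROTEIN, source: Analytical_sample, target: Modified_protein}
  - {type: HAS_QUANTIFIED_CLINICAL, source: Biological_sample, target: Clinical_variable}
  - {type: HAS_ENROLLED, source: Project, target: Subject}
  - {type: HAS_BIOLOGICAL_SAMPLE, source: Subject, target: Biological_sample}
  - {type: SPLITTED_INTO, source: Biological_sample, target: Analytical_sample}
  - {type: BELONGS_TO_PROJECT, source: Analytical_sample, target: Project}
  - {type: STUDIES_DISEASE, source: Project, target: Disease}
  - {type: STUDIES_TISSUE, source: Project, target: Tissue}
  - {type: STUDIES_INTERVENTION, source: Project, target: Clinical_variable}
  - {type: HAS_DISEASE, source: Biological_sample, target: Disease}
  - {type: FROM_TISSUE, source: Biological_sample, target: Tissue}
  - {type: SAMPLE_AT_TIMEPOINT, source: Biological_sample, target: Timepoint}
  - {type: IS_RESPONSIBLE, source: User, target: Project}
  - {type: TRANSCRIBED_INTO, source: Gene, target: Transcript}
  - {type: TRANSLATED_INTO, source: Transcript, target: Protein}
  - {type: LOCATED_IN, source: Gene, target: Chromosome}
  - {type: LOCATED_IN, source: Functional_region, target: Protein}
  - {type: HAS_SEQUENCE, source: Protein, target: Amino_acid_sequence}
  - {type: HAS_STRUCTURE, source: Protein, target: Protein_structure}
  - {type: HAS_MODIFIED_SITE, source: Protein, target: Modified_protein}
  - {type: HAS_MODIFICATION, source: Modified_protein, target: Modification}
  - {type: IS_SUBSTRATE_OF, source: Modified_protein, target: Protein}
  - {type: IS_SUBSTRATE_OF, source: Protein, target: Protein}
  - {type: CURATED_INTERACTS_WITH, source: Protein, target: Protein}
  - {type: COMPILED_INTERACTS_WITH, source: Protein, target: Protein}
  - {type: ACTS_ON, source: Drug, target: Protein}
  - {type: HAS_SIDE_EFFECT, source: Drug, target: Side_effect}
  - {type: INDICATED_FOR, source: Drug, target: Disease}
  - {type: ANNOTATED_IN_PATHWAY, source: Protein, target: Pathway}
  - {type: ANNOTATED_IN_PATHWAY, source: Metabolite, target: Pathway}
  - {type: ANNOTATED_IN_PATHWAY, source: Drug, target: Pathway}
  - {type: MENTIONED_IN_PUBLICATION, source: Protein, target: Publication}
  - {type: MENTIONED_IN_PUBLICATION, source: Drug, target: Publication}
  - {type: MENTIONED_IN_PUBLICATION, source: Disease, target: Publication}
  - {type: MENTIONED_IN_PUBLICATION, source: Metabolite, target: Publication}
  - {type: MENTIONED_IN_PUBLICATION, source: Tissue, target: Publication}
  - {type: IS_BIOMARKER_OF_DISEASE, source: Protein, target: Disease}
  - {type: IS_QCMARKER_IN_TISSUE, source: Protein, target: Tissue}
  - {type: DETECTED_IN_PATHOLOGY_SAMPLE, source: Protein, target: Disease}
  - {type: VARIANT_FOUND_IN_GENE, source: Known_variant, target: Gene}
  - {type: VARIANT_FOUND_IN_CHROMOSOME, source: Known_variant, target: Chromosome}
  - {type: VARIANT_IS_CLINICALLY_RELEVANT, source: Known_variant, target: Clinically_relevant_variant}
  - {type: TARGETS_CLINICALLY_RELEVANT_VARIANT, source: Drug, target: Clinically_relevant_variant}
  - {type: VARIANT_FOUND_IN_GWAS, source: Known_variant, target: GWAS_study}
  - {type: STUDIES_TRAIT, source: GWAS_study, target: Phenotype}
  - {type: HAS_COMPONENT, source: Complex, target: Protein}
  - {type: FOUND_IN_FOOD, source: Metabolite, target: Food}
  - {type: IS_REGULATED_BY, source: Gene, target: Transcription_factor}
  - {type: MAPS_TO, source: Peptide, target: Protein}
  - {type: HAS_PHENOTYPE, source: Disease, target: Phenotype}
  - {type: INTERACTS_WITH_DRUG, source: Drug, target: Drug}
required_attributes:
  nodes:
    Project: [name]
    Clinical_variable: [name]
  edges:
    HAS_QUANTIFIED_PROTEIN: [value]
    HAS_QUANTIFIED_PEPTIDE: [value]
    HAS_QUANTIFIED_MODIFIED_PROTEIN: [value]
    HAS_QUANTIFIED_CLINICAL: [value]
    ACTS_ON: [action]
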