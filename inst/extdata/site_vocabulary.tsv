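# Primary-site code -> growth class used by the modified Katagiri score.
# Edit a copy and pass it to site_vocabulary(path = ...) to override.
# Unlisted sites must be mapped to "other" (moderate) deliberately by the
# caller; "unknown_origin" (occult primary) is rapid.
site	growth_class
breast	slow
prostate	slow
thyroid	slow
multiple_myeloma	slow
lymphoma	slow
renal_cell	moderate
endometrial	moderate
ovarian	moderate
sarcoma	moderate
other	moderate
lung	rapid
colorectal	rapid
gastric	rapid
pancreatic	rapid
head_and_neck	rapid
esophageal	rapid
other_urological	rapid
melanoma	rapid
hepatocellular	rapid
gall_bladder	rapid
cervical	rapid
unknown_origin	rapid
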