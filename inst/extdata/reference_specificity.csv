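experiment,feature,variant,class,specificity_pct
augmentation,histogram,without,meningioma,88.2
augmentation,histogram,without,glioma,86.1
augmentation,histogram,without,pituitary,82.6
augmentation,histogram,with,meningioma,92.4
augmentation,histogram,with,glioma,90.6
augmentation,histogram,with,pituitary,90.2
augmentation,glcm_element,without,meningioma,91.3
augmentation,glcm_element,without,glioma,88.3
augmentation,glcm_element,without,pituitary,87.2
augmentation,glcm_element,with,meningioma,92.7
augmentation,glcm_element,with,glioma,92.3
augmentation,glcm_element,with,pituitary,92.1
augmentation,bow,without,meningioma,93.5
augmentation,bow,without,glioma,91.3
augmentation,bow,without,pituitary,90.3
augmentation,bow,with,meningioma,94.9
augmentation,bow,with,glioma,93.2
augmentation,bow,with,pituitary,93.6
partition,histogram,without,meningioma,92.3
partition,histogram,without,glioma,91.1
partition,histogram,without,pituitary,90.1
partition,histogram,with,meningioma,92.9
partition,histogram,with,glioma,95.5
partition,histogram,with,pituitary,93.4
partition,glcm_element,without,meningioma,94.3
partition,glcm_element,without,glioma,92.8
partition,glcm_element,without,pituitary,92.0
partition,glcm_element,with,meningioma,94.7
partition,glcm_element,with,glioma,96.0
partition,glcm_element,with,pituitary,94.1
partition,bow,without,meningioma,94.9
partition,bow,without,glioma,92.9
partition,bow,without,pituitary,93.4
partition,bow,with,meningioma,95.5
partition,bow,with,glioma,96.3
partition,bow,with,pituitary,95.3
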